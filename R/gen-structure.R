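# Synthetic C-alpha structure generation from secondary-structure plans.
# Helices use ideal alpha geometry (2.3 A radius, 1.5 A rise, 100 deg/residue);
# strands extended geometry (3.4 A rise, alternating +/-0.85 A lateral offset,
# consecutive distance 3.8 A); coils are smooth random walks with step
# 3.8 +/- 0.1 A and turning angles in 70-120 deg, which keeps them clear of
# both the helix and strand short-range distance windows.

#' Construct a structure model
#'
#' The unit of the structure database: an ordered C-alpha trace with a
#' per-residue confidence (pLDDT-like, 0-100).
#'
#' @param id Protein id.
#' @param xyz Numeric N x 3 matrix of C-alpha coordinates (Angstrom).
#' @param confidence Numeric vector of length N in `[0, 100]`.
#' @param resno Residue numbers (default `1:N`).
#' @return A `structure_model` object.
#' @export
structure_model <- function(id, xyz, confidence = rep(90, nrow(xyz)),
                            resno = seq_len(nrow(xyz))) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) >= 3, length(confidence) == nrow(xyz))
  structure(
    list(id = id, xyz = unname(xyz), confidence = as.numeric(confidence),
         resno = as.integer(resno)),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d residues, mean confidence %.1f\n",
              x$id, nrow(x$xyz), mean(x$confidence)))
  invisible(x)
}

#' @export
length.structure_model <- function(x) nrow(x$xyz)

#' Tidy a structure model into a residue table
#'
#' @param x A `structure_model`.
#' @param ... Unused.
#' @return A tibble with one row per residue: `resno`, `x`, `y`, `z`,
#'   `confidence`.
#' @export
tidy.structure_model <- function(x, ...) {
  tibble::tibble(
    resno = x$resno, x = x$xyz[, 1], y = x$xyz[, 2], z = x$xyz[, 3],
    confidence = x$confidence
  )
}

#' Generate a synthetic C-alpha model from a secondary-structure plan
#'
#' Segments are built on ideal local geometry, joined at 3.8 A with seeded
#' random orientations, and perturbed by isotropic Gaussian coordinate noise.
#' Per-residue confidence is written as 90 for helix/strand residues and 50
#' for coils (mimicking the pLDDT habit of scoring ordered regions higher;
#' the screen deliberately never filters on it).
#'
#' @param sse_plan Tibble/data.frame with columns `type` (`"H"`, `"E"`,
#'   `"coil"`) and `length` (residues, >= 1).
#' @param noise_sigma Isotropic Gaussian noise s.d. per coordinate (A, >= 0).
#' @param seed Integer seed.
#' @param id Protein id stamped on the model.
#' @return A [structure_model()].
#' @export
gen_structure <- function(sse_plan, noise_sigma = 0, seed = 1L, id = "synthetic") {
  sse_plan <- tibble::as_tibble(sse_plan)
  stopifnot(all(sse_plan$length >= 1), noise_sigma >= 0,
            all(sse_plan$type %in% c("H", "E", "coil")))
  withr::with_seed(as.integer(seed), {
    coords <- NULL
    conf <- numeric(0)
    for (i in seq_len(nrow(sse_plan))) {
      seg <- build_segment(sse_plan$type[i], sse_plan$length[i])
      rot <- random_rotation()
      seg <- seg %*% t(rot)
      if (is.null(coords)) {
        coords <- seg
      } else {
        u <- random_unit()
        start <- coords[nrow(coords), ] + 3.8 * u
        seg <- sweep(seg, 2, seg[1, ] - start, "-")
        coords <- rbind(coords, seg)
      }
      conf <- c(conf, rep(if (sse_plan$type[i] == "coil") 50 else 90, sse_plan$length[i]))
    }
    if (noise_sigma > 0) {
      coords <- coords + matrix(rnorm(length(coords), sd = noise_sigma), ncol = 3)
    }
    structure_model(id, coords, conf)
  })
}

build_segment <- function(type, n) {
  k <- seq_len(n) - 1
  if (type == "H") {
    th <- k * 100 * pi / 180
    cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * k)
  } else if (type == "E") {
    cbind(0.85 * (-1)^k, 0, 3.4 * k)
  } else {
    # random walk with step 3.8 +/- 0.1 A and turning angles in 100-140
    # degrees: sharp enough that neither the helix (65-96 deg) nor the
    # strand (<= 65 deg) short-range distance window can be satisfied, so
    # coils stay coils under assignment
    pos <- matrix(0, n, 3)
    d <- random_unit()
    if (n > 1) {
      for (i in 2:n) {
        step <- 3.8 + rnorm(1, sd = 0.03)
        pos[i, ] <- pos[i - 1, ] + step * d
        theta <- runif(1, 100, 140) * pi / 180
        perp <- random_perpendicular(d)
        d <- cos(theta) * d + sin(theta) * perp
        d <- d / sqrt(sum(d^2))
      }
    }
    pos
  }
}

random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

random_perpendicular <- function(d) {
  v <- rnorm(3)
  v <- v - sum(v * d) * d
  v / sqrt(sum(v^2))
}

# Uniform random proper rotation (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Add isotropic Gaussian coordinate noise to a model
#'
#' Used to derive planted-analog structures that share a template's fold.
#'
#' @param model A [structure_model()].
#' @param sigma Noise s.d. per coordinate (A).
#' @param seed Integer seed.
#' @param id Optional new id.
#' @return A [structure_model()].
#' @export
perturb_structure <- function(model, sigma, seed, id = model$id) {
  withr::with_seed(as.integer(seed), {
    xyz <- model$xyz + matrix(rnorm(length(model$xyz), sd = sigma), ncol = 3)
    structure_model(id, xyz, model$confidence, model$resno)
  })
}

#' Write a structure model as a PDB coordinate file
#'
#' One chain, one model, CA atoms only; confidence goes to the B-factor
#' column, residue numbering starts at 1.
#'
#' @param model A [structure_model()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  n <- nrow(model$xyz)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(model$xyz)),
    resno = model$resno,
    resid = rep("ALA", n),
    elety = rep("CA", n),
    chain = rep("A", n),
    b = round(model$confidence, 2)
  )
  invisible(path)
}
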