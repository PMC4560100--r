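#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation (3x3 orthonormal matrix with
#' determinant +1) followed by a translation: `y = R x + t`.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector (Angstrom).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    abort("rotation matrix is not orthonormal")
  }
  if (abs(det(rotation) - 1) > 1e-6) {
    abort("rotation matrix must have determinant +1 (proper rotation)")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  d <- decompose_transform(x)
  cat(sprintf("<rigid_transform> rotation %.2f deg about (%.3f, %.3f, %.3f), translation (%.2f, %.2f, %.2f) A\n",
              d$angle_deg, d$axis[1], d$axis[2], d$axis[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' @rdname rigid_transform
#' @param x Coordinates: an n x 3 matrix or an atom tibble.
#' @param tf A `rigid_transform`.
#' @return `apply_transform()`: the transformed object, same type as `x`.
#' @export
apply_transform <- function(x, tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (is.matrix(x)) {
    out <- x %*% t(tf$rotation)
    out <- sweep(out, 2, tf$translation, "+")
    return(out)
  }
  if (is.data.frame(x)) {
    m <- cbind(x$x, x$y, x$z) %*% t(tf$rotation)
    x$x <- m[, 1] + tf$translation[1]
    x$y <- m[, 2] + tf$translation[2]
    x$z <- m[, 3] + tf$translation[3]
    return(x)
  }
  abort("x must be a coordinate matrix or an atom tibble")
}

#' @rdname rigid_transform
#' @param first,second Transforms; the result applies `first`, then
#'   `second`.
#' @export
compose_transforms <- function(first, second) {
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) +
                    second$translation)
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), -as.numeric(t(tf$rotation) %*% tf$translation))
}

#' @rdname rigid_transform
#' @param axis Rotation axis (length-3, need not be unit).
#' @param angle_deg Rotation angle in degrees.
#' @param center Point the axis passes through.
#' @export
rotation_about <- function(axis, angle_deg, center = c(0, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigid_transform(R, as.numeric(center - R %*% center))
}

coords_of <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(unname(x))
  }
  if (is.data.frame(x)) return(unname(ca_coords(x)[, , drop = FALSE]))
  abort("expected an n x 3 coordinate matrix or an atom tibble")
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired coordinate sets (row i of `mobile` pairs with row i of
#' `reference`). Atom tibbles are reduced to their CA trace in residue
#' order.
#'
#' @param mobile,reference Paired coordinates: n x 3 matrices or atom
#'   tibbles with equal residue counts, n >= 3, non-degenerate.
#' @return A list of class `superposition`: `transform` (the
#'   `rigid_transform` mapping mobile onto reference) and `rmsd` (Angstrom,
#'   after the fit).
#' @examples
#' m <- matrix(rnorm(30), 10, 3)
#' tf <- rotation_about(c(0, 0, 1), 90)
#' fit <- superpose(apply_transform(m, tf), m)
#' fit$rmsd
#' @export
superpose <- function(mobile, reference) {
  M <- coords_of(mobile)
  Rf <- coords_of(reference)
  if (nrow(M) != nrow(Rf)) {
    abort(paste0("length mismatch: ", nrow(M), " vs ", nrow(Rf), " positions"))
  }
  if (nrow(M) < 3) abort("need at least 3 paired positions")
  tf <- kabsch(M, Rf)
  fitted <- apply_transform(M, tf)
  rmsd <- sqrt(mean(rowSums((fitted - Rf)^2)))
  structure(list(transform = tf, rmsd = rmsd), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A\n", x$rmsd))
  print(x$transform)
  invisible(x)
}

kabsch <- function(M, Rf) {
  cm <- colMeans(M)
  cr <- colMeans(Rf)
  Mc <- sweep(M, 2, cm)
  Rc <- sweep(Rf, 2, cr)
  if (max(svd(Mc)$d[2], svd(Rc)$d[2]) < 1e-9) {
    abort("degenerate (collinear or coincident) coordinates")
  }
  A <- crossprod(Mc, Rc) # 3x3
  sv <- svd(A)
  d <- sign(det(sv$v %*% t(sv$u)))
  Rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(Rot, as.numeric(cr - Rot %*% cm))
}

#' Membrane coordinate frame
#'
#' Defines the membrane normal and origin used to express displacements.
#' The default assumes membrane-oriented coordinates (e.g. OPM convention)
#' with the normal along the laboratory z axis, in which case the frame
#' basis is the identity.
#'
#' @param normal Membrane normal (length-3, normalised internally).
#' @param origin Frame origin (Angstrom).
#' @return A list of class `membrane_frame` with unit `normal`, `origin`
#'   and a 3x3 `basis` matrix whose columns are the in-plane x, y axes and
#'   the normal.
#' @export
membrane_frame <- function(normal = c(0, 0, 1), origin = c(0, 0, 0)) {
  n <- normal / sqrt(sum(normal^2))
  if (abs(n[3]) > 0.999999) {
    # membrane-oriented input: frame is the laboratory frame
    n <- c(0, 0, 1) * sign(n[3])
    b1 <- c(1, 0, 0)
    b2 <- c(0, 1, 0) * sign(n[3])
  } else {
    b1 <- vcross(c(0, 0, 1), n)
    b1 <- b1 / sqrt(sum(b1^2))
    b2 <- vcross(n, b1)
  }
  structure(list(normal = n, origin = as.numeric(origin),
                 basis = cbind(b1, b2, n)),
            class = "membrane_frame")
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Decompose a rigid transform into axis, angle and frame displacement
#'
#' Extracts the rotation angle (from the matrix trace), the rotation axis
#' (from the antisymmetric part; near 180 degrees from the dominant
#' eigenvector of the symmetric part), the displacement of a reference
#' centroid expressed in the membrane frame, and the angle between the
#' rotation axis and the membrane normal (folded into [0, 90] degrees,
#' since the axis sign is conventional).
#'
#' @param tf A `rigid_transform`.
#' @param frame A [membrane_frame()].
#' @param centroid Point whose displacement is reported (typically the
#'   transport-domain centroid), laboratory coordinates.
#' @return A list of class `motion_decomposition`: `angle_deg` in
#'   [0, 180], unit `axis`, `displacement` (`dx`, `dy`, `dz` in the frame),
#'   `axis_membrane_angle_deg`.
#' @export
decompose_transform <- function(tf, frame = membrane_frame(),
                                centroid = c(0, 0, 0)) {
  R <- tf$rotation
  tr <- sum(diag(R))
  angle <- acos(pmin(1, pmax(-1, (tr - 1) / 2)))
  if (angle < 1e-9) {
    axis <- frame$normal
  } else if (angle < pi - 1e-4) {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(angle))
  } else {
    S <- (R + diag(3)) / 2
    ev <- eigen(S, symmetric = TRUE)
    axis <- ev$vectors[, which.max(ev$values)]
  }
  axis <- axis / sqrt(sum(axis^2))
  disp <- apply_transform(matrix(centroid, 1, 3), tf)[1, ] - centroid
  disp_frame <- as.numeric(t(frame$basis) %*% disp)
  # axis sign is conventional, so fold the axis/normal angle into [0, 90]
  ax_angle <- acos(pmin(1, abs(sum(axis * frame$normal)))) * 180 / pi
  structure(list(
    angle_deg = angle * 180 / pi,
    axis = as.numeric(axis),
    displacement = setNames(disp_frame, c("dx", "dy", "dz")),
    axis_membrane_angle_deg = ax_angle
  ), class = "motion_decomposition")
}

#' @export
print.motion_decomposition <- function(x, ...) {
  cat(sprintf("<motion> %.2f deg about (%.3f, %.3f, %.3f); displacement (%.2f, %.2f, %.2f) A; axis-normal angle %.1f deg\n",
              x$angle_deg, x$axis[1], x$axis[2], x$axis[3],
              x$displacement[1], x$displacement[2], x$displacement[3],
              x$axis_membrane_angle_deg))
  invisible(x)
}

#' @rdname decompose_transform
#' @param x A `motion_decomposition`.
#' @param ... Unused.
#' @method as_tibble motion_decomposition
#' @export
as_tibble.motion_decomposition <- function(x, ...) {
  tibble(
    angle_deg = x$angle_deg,
    axis_x = x$axis[1], axis_y = x$axis[2], axis_z = x$axis[3],
    dx = unname(x$displacement[1]), dy = unname(x$displacement[2]),
    dz = unname(x$displacement[3]),
    axis_membrane_angle_deg = x$axis_membrane_angle_deg
  )
}

# d0 of the TM-score, clamped below at 0.5 (the published formula is
# negative for normalisation lengths below ~21 residues)
tm_d0 <- function(l_norm) {
  s <- l_norm - 15
  if (s <= 0) return(0.5)
  max(0.5, 1.24 * s^(1 / 3) - 1.8)
}

#' Template modeling score (TM-score)
#'
#' Length-normalised structural similarity between paired coordinate sets:
#' `TM = max over superpositions of (1/l_norm) * sum_i 1/(1 + (d_i/d0)^2)`
#' with `d0 = 1.24 (l_norm - 15)^(1/3) - 1.8`, clamped below at 0.5. The
#' maximisation uses the standard iterative fragment search: seed fragments
#' of length n, n/2 and n/4 are superposed, the close pairs (d < d0-based
#' cutoff) are re-fit until the selected set is stable, and the best score
#' over all seeds is kept.
#'
#' @param mobile,reference Paired coordinates (n x 3 matrices or atom
#'   tibbles), rows corresponding; n >= 3.
#' @param l_norm Normalisation length (>= n); defaults to the number of
#'   reference positions.
#' @param optimize If `FALSE`, score the pairing as given (identity pose,
#'   no superposition search) - the bare scoring formula.
#' @return The TM-score in (0, 1], with the best transform attached as
#'   attribute `transform`.
#' @export
tm_score <- function(mobile, reference, l_norm = NULL, optimize = TRUE) {
  M <- coords_of(mobile)
  Rf <- coords_of(reference)
  n <- nrow(M)
  if (nrow(Rf) != n) abort("mobile and reference must have equal lengths")
  if (n < 3) abort("need at least 3 aligned pairs")
  l_norm <- l_norm %||% n
  if (l_norm < n) abort("l_norm must be at least the number of aligned pairs")
  d0 <- tm_d0(l_norm)
  score_of <- function(Mt) {
    d2 <- rowSums((Mt - Rf)^2)
    sum(1 / (1 + d2 / d0^2)) / l_norm
  }
  if (!optimize) {
    return(structure(score_of(M), transform = rigid_transform()))
  }
  best <- -Inf
  best_tf <- NULL
  if (n <= 8) {
    # tiny inputs: seed every aligned subset of size >= 3 (exhaustive)
    seeds <- list()
    for (mask in 1:(2^n - 1)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      if (length(idx) >= 3) seeds[[length(seeds) + 1]] <- idx
    }
  } else if (n <= 12) {
    # every contiguous window
    seeds <- list()
    for (len in 3:n) {
      for (st in seq(1L, n - len + 1L)) {
        seeds[[length(seeds) + 1]] <- st:(st + len - 1L)
      }
    }
  } else {
    seeds <- list()
    for (len in unique(pmax(3L, c(n, floor(n / 2), floor(n / 4))))) {
      for (st in unique(c(seq(1L, n - len + 1L, by = max(1L, floor(len / 2))),
                          n - len + 1L))) {
        seeds[[length(seeds) + 1]] <- st:(st + len - 1L)
      }
    }
  }
  for (seed_idx in seeds) {
    idx <- seed_idx
    for (iter in 1:20) {
      tf <- tryCatch(kabsch(M[idx, , drop = FALSE], Rf[idx, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(tf)) break
      Mt <- apply_transform(M, tf)
      sc <- score_of(Mt)
      if (sc > best) {
        best <- sc
        best_tf <- tf
      }
      d <- sqrt(rowSums((Mt - Rf)^2))
      cut <- d0
      sel <- which(d < cut)
      while (length(sel) < 3) {
        cut <- cut + 0.5
        sel <- which(d < cut)
      }
      if (length(sel) == length(idx) && all(sel == idx)) break
      idx <- sel
    }
  }
  structure(best, transform = best_tf)
}

#' Per-residue displacement profile
#'
#' Superposes `model` onto `reference` using only the CA atoms inside
#' `fit_ranges` (typically the scaffold domain), then reports the CA-CA
#' distance for every residue shared by both structures - the standard
#' way to visualise which parts of a transporter move between
#' conformations.
#'
#' @param model,reference Atom tibbles sharing residue numbering.
#' @param fit_ranges Residue ranges used for the superposition fit.
#' @return A tibble `(chain_id, res_seq, displacement_A)` in reference
#'   residue order, with the fit RMSD as attribute `fit_rmsd`.
#' @export
displacement_profile <- function(model, reference, fit_ranges) {
  fit_ranges <- if (is.data.frame(fit_ranges)) validate_ranges(as_tibble(fit_ranges)) else residue_ranges(fit_ranges)
  cm <- ca_coords(model)
  cr <- ca_coords(reference)
  key_m <- rownames(cm)
  key_r <- rownames(cr)
  shared <- intersect(key_r, key_m)
  if (length(shared) == 0) abort("no shared residues between model and reference")
  im <- match(shared, key_m)
  ir <- match(shared, key_r)
  ch <- attr(cr, "chain_id")[ir]
  rs <- attr(cr, "res_seq")[ir]
  infit <- in_ranges(ch, rs, fit_ranges)
  if (sum(infit) < 3) abort("fewer than 3 shared residues in fit_ranges")
  fit <- superpose(cm[im[infit], , drop = FALSE], cr[ir[infit], , drop = FALSE])
  fitted <- apply_transform(cm[im, , drop = FALSE], fit$transform)
  d <- sqrt(rowSums((fitted - cr[ir, , drop = FALSE])^2))
  out <- tibble(chain_id = ch, res_seq = rs, displacement_A = d)
  out <- out[order(ir), , drop = FALSE]
  attr(out, "fit_rmsd") <- fit$rmsd
  out
}
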