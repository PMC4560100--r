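#' Specification of a synthetic two-repeat toy transporter
#'
#' The generator builds a membrane-protein-like toy with the
#' inverted-topology architecture: repeat unit 1 is a bundle of ideal
#' poly-alanine helices (rise 1.5 A per residue, 100 degrees per residue)
#' spanning the membrane along z; repeat unit 2 is RU1 mapped through an
#' exact two-fold rotation about an in-plane axis (the pseudo-symmetry of
#' inverted repeats); and the conformational asymmetry between the repeats
#' is a rigid swing of RU2's transport sub-repeat about an in-plane axis
#' through its scaffold anchor, plus a shift along the membrane normal.
#' Loops are straight-line glycine connectors flagged as coil.
#'
#' The transport helices sit at the lever distance
#' `shift / sin(angle)` from the swing axis, so the normal shift counters
#' the lever drop: the asymmetric repeat keeps its helix register
#' recoverable by automatic structural alignment (in real applications
#' register errors are fixed by manual alignment refinement, which a
#' generator cannot emulate).
#'
#' @param helices_per_repeat Helices per repeat unit (>= 2); the first half
#'   (rounded up) form the scaffold sub-repeat, the rest the transport
#'   sub-repeat.
#' @param helix_length Residues per helix.
#' @param asymmetry_angle_deg Swing (degrees) of RU2's transport
#'   sub-repeat.
#' @param asymmetry_shift_A Accompanying translation along the membrane
#'   normal (Angstrom).
#' @param peripheral_helices Helices outside both repeats (>= 0).
#' @param noise_A Gaussian coordinate jitter sigma (Angstrom).
#' @param linker_length Residues per straight-line connector.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A list of class `toy_spec`.
#' @export
toy_spec <- function(helices_per_repeat = 4L, helix_length = 12L,
                     asymmetry_angle_deg = 20, asymmetry_shift_A = 5,
                     peripheral_helices = 1L, noise_A = 0.3,
                     linker_length = 3L, seed = 1L) {
  stopifnot(helices_per_repeat >= 2, helix_length >= 4,
            asymmetry_angle_deg >= 0, asymmetry_shift_A >= 0,
            peripheral_helices >= 0, noise_A >= 0)
  structure(list(
    helices_per_repeat = as.integer(helices_per_repeat),
    helix_length = as.integer(helix_length),
    asymmetry_angle_deg = asymmetry_angle_deg,
    asymmetry_shift_A = asymmetry_shift_A,
    peripheral_helices = as.integer(peripheral_helices),
    noise_A = noise_A,
    linker_length = as.integer(linker_length),
    seed = as.integer(seed)
  ), class = "toy_spec")
}

# ideal helix CA trace plus schematic N, C, O carriers
helix_atoms <- function(center, direction, n_res, res_name = "ALA",
                        rise = 1.5, twist_deg = 100, radius = 2.3) {
  a <- direction / sqrt(sum(direction^2))
  u <- if (abs(a[1]) < 0.9) vcross(a, c(1, 0, 0)) else vcross(a, c(0, 1, 0))
  u <- u / sqrt(sum(u^2))
  v <- vcross(a, u)
  j <- seq_len(n_res) - 1
  t_ <- (j - (n_res - 1) / 2) * rise
  th <- j * twist_deg * pi / 180
  ca <- t(vapply(seq_along(j), function(k) {
    center + a * t_[k] + radius * (cos(th[k]) * u + sin(th[k]) * v)
  }, numeric(3)))
  backbone_from_ca(ca, res_name)
}

# place schematic N, C, O around a CA trace (format-valid carriers; all
# quantitative analysis in the package uses CA only)
backbone_from_ca <- function(ca, res_name) {
  n <- nrow(ca)
  nxt <- rbind(ca[-1, , drop = FALSE], ca[n, , drop = FALSE] +
                 (ca[n, ] - ca[max(1, n - 1), ]))
  prv <- rbind(ca[1, , drop = FALSE] - (ca[min(2, n), ] - ca[1, ]),
               ca[-n, , drop = FALSE])
  res <- lapply(seq_len(n), function(k) {
    dn <- prv[k, ] - ca[k, ]
    dc <- nxt[k, ] - ca[k, ]
    dn <- if (sum(dn^2) > 0) dn / sqrt(sum(dn^2)) else c(-1, 0, 0)
    dc <- if (sum(dc^2) > 0) dc / sqrt(sum(dc^2)) else c(1, 0, 0)
    up <- vcross(dn, dc)
    up <- if (sum(up^2) > 1e-8) up / sqrt(sum(up^2)) else c(0, 0, 1)
    pos <- rbind(ca[k, ] + 1.46 * dn, ca[k, ], ca[k, ] + 1.52 * dc,
                 ca[k, ] + 1.52 * dc + 1.23 * up)
    tibble(name = c("N", "CA", "C", "O"), x = pos[, 1], y = pos[, 2],
           z = pos[, 3], element = c("N", "C", "C", "O"),
           res_name = res_name)
  })
  bind_rows(res)
}

linker_atoms <- function(from, to, n_res) {
  if (n_res == 0) return(tibble())
  f <- seq_len(n_res) / (n_res + 1)
  ca <- t(vapply(f, function(w) (1 - w) * from + w * to, numeric(3)))
  backbone_from_ca(ca, "GLY")
}

#' Generate a toy inverted-repeat transporter with known ground truth
#'
#' Builds the structure described by [toy_spec()] and records everything a
#' test needs as ground truth: the exact two-fold symmetry operation
#' relating the repeats (180 degrees about an in-plane axis, before
#' asymmetry), the true RU1/RU2 residue correspondence, the asymmetry
#' parameters, the true swapped-conformation structure (see
#' [make_swapped_truth()]), and the exact transport-domain motion between
#' the original and swapped conformations (Kabsch fit of the generator's
#' own truth pair - the oracle downstream analyses must recover).
#'
#' @param spec A [toy_spec()].
#' @return A list with `structure` (atom tibble), `truth` (class
#'   `toy_truth`), `repeats` (a [repeat_definition()]) and `domains`
#'   (a [domain_definition()]).
#' @export
make_toy_transporter <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  H <- spec$helices_per_repeat
  n_scaf <- ceiling(H / 2)
  n_trans <- H - n_scaf
  hl <- spec$helix_length
  ll <- spec$linker_length
  alpha <- spec$asymmetry_angle_deg * pi / 180

  # lever distance from the scaffold anchor to the transport helices: the
  # membrane-normal shift cancels the swing's drop along the helix axes
  scaf_x <- (seq_len(n_scaf) - 1) * 5
  lever <- if (alpha > 1e-6) spec$asymmetry_shift_A / sin(alpha) else 15
  trans_x <- mean(scaf_x) + max(lever, 8)
  trans_y_off <- (seq_len(max(n_trans, 1)) - 1) * 5

  y0 <- 6
  centers <- list()
  dirs <- list()
  part <- character(0)
  for (k in seq_len(n_scaf)) {
    centers[[length(centers) + 1]] <- c(scaf_x[k], y0 + (k %% 2), 0)
    dirs[[length(dirs) + 1]] <- c(0, 0, ifelse(k %% 2 == 1, 1, -1))
    part <- c(part, "scaffold")
  }
  for (k in seq_len(n_trans)) {
    centers[[length(centers) + 1]] <- c(trans_x, y0 - 2 + trans_y_off[k], 0)
    dirs[[length(dirs) + 1]] <- c(0, 0, ifelse(k %% 2 == 1, 1, -1))
    part <- c(part, "transport")
  }

  # RU1 atoms, helix by helix with connectors
  ru_atoms <- list()
  res_part <- character(0)
  for (k in seq_along(centers)) {
    h <- helix_atoms(centers[[k]], dirs[[k]], hl)
    ru_atoms[[length(ru_atoms) + 1]] <- h
    res_part <- c(res_part, rep(part[k], hl))
    if (k < length(centers)) {
      from <- as.numeric(h[h$name == "CA", c("x", "y", "z")][hl, ])
      nx <- helix_atoms(centers[[k + 1]], dirs[[k + 1]], hl)
      to <- as.numeric(nx[nx$name == "CA", c("x", "y", "z")][1, ])
      lk <- linker_atoms(from, to, ll)
      ru_atoms[[length(ru_atoms) + 1]] <- lk
      # hinge connector between sub-repeats stays with the earlier part
      res_part <- c(res_part, rep(part[k], ll))
    }
  }
  ru1 <- bind_rows(ru_atoms)
  n_ru <- length(res_part) # residues per repeat unit

  # peripheral helices on the symmetry axis side
  periph <- list()
  if (spec$peripheral_helices > 0) {
    for (k in seq_len(spec$peripheral_helices)) {
      periph[[k]] <- helix_atoms(c(-7 - 5 * (k - 1), 3, 0),
                                 c(0, 0, ifelse(k %% 2 == 1, 1, -1)), hl)
    }
  }
  periph <- if (length(periph)) bind_rows(periph) else tibble()
  n_periph <- if (nrow(periph)) spec$peripheral_helices * hl else 0L

  c2 <- rigid_transform(diag(c(1, -1, -1)), c(0, 0, 0))
  ru2 <- apply_transform(ru1, c2)

  assemble <- function(ru1a, periph_a, ru2a) {
    pieces <- list(ru1a)
    if (nrow(periph) > 0) pieces[[length(pieces) + 1]] <- periph_a
    pieces[[length(pieces) + 1]] <- ru2a
    at <- bind_rows(pieces)
    res_id <- rep(seq_len(2 * n_ru + n_periph), each = 4)
    at$serial <- seq_len(nrow(at))
    at$altloc <- " "
    at$chain_id <- "A"
    at$res_seq <- res_id
    at$i_code <- " "
    at$occupancy <- 1
    at$is_hetatm <- FALSE
    at[, c("serial", "name", "altloc", "res_name", "chain_id", "res_seq",
           "i_code", "x", "y", "z", "occupancy", "element", "is_hetatm")]
  }

  # residue bookkeeping (1-based, chain A): RU1, peripheral, RU2
  ru1_range <- c(1L, n_ru)
  periph_range <- if (n_periph > 0) c(n_ru + 1L, n_ru + n_periph) else NULL
  ru2_start <- n_ru + n_periph + 1L
  ru2_range <- c(ru2_start, ru2_start + n_ru - 1L)

  trans_local <- which(res_part == "transport") # within-repeat indices
  scaf_local <- which(res_part == "scaffold")

  # asymmetry: swing RU2's transport sub-repeat about the in-plane y axis
  # through RU2's scaffold-anchor centroid, then shift along the normal
  ru2_ca <- ru2[ru2$name == "CA", , drop = FALSE]
  anchor <- colMeans(cbind(ru2_ca$x, ru2_ca$y, ru2_ca$z)[scaf_local, , drop = FALSE])
  swing <- compose_transforms(
    rotation_about(c(0, 1, 0), spec$asymmetry_angle_deg, center = anchor),
    rigid_transform(diag(3), c(0, 0, spec$asymmetry_shift_A))
  )
  trans_rows <- rep(seq_len(n_ru) %in% trans_local, each = 4)
  ru2_asym <- ru2
  ru2_asym[trans_rows, c("x", "y", "z")] <-
    apply_transform(ru2[trans_rows, , drop = FALSE], swing)[, c("x", "y", "z")]

  x_struct <- assemble(ru1, periph, ru2_asym)

  # deterministic jitter, seeded from the spec
  if (spec$noise_A > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(spec$seed)
    x_struct$x <- x_struct$x + rnorm(nrow(x_struct), 0, spec$noise_A)
    x_struct$y <- x_struct$y + rnorm(nrow(x_struct), 0, spec$noise_A)
    x_struct$z <- x_struct$z + rnorm(nrow(x_struct), 0, spec$noise_A)
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }
  attr(x_struct, "title") <- "synthetic inverted-repeat toy transporter"
  attr(x_struct, "provenance") <- paste0("make_toy_transporter(seed=", spec$seed, ")")

  rng <- function(lo_hi) paste0("A:", lo_hi[1], "-", lo_hi[2])
  repeats <- repeat_definition(
    rng(ru1_range), rng(ru2_range),
    peripheral = if (!is.null(periph_range)) rng(periph_range) else NULL
  )
  seg_ranges <- function(local_idx) {
    # contiguous runs of within-repeat indices, mapped to both repeats
    runs <- split(local_idx, cumsum(c(1L, diff(local_idx) != 1L)))
    unlist(lapply(runs, function(ix) {
      c(paste0("A:", ix[1], "-", ix[length(ix)]),
        paste0("A:", ru2_start + ix[1] - 1L, "-", ru2_start + ix[length(ix)] - 1L))
    }))
  }
  domains <- domain_definition(
    paste(seg_ranges(scaf_local), collapse = ","),
    paste(seg_ranges(trans_local), collapse = ",")
  )

  correspondence <- tibble(
    res_ru1 = seq_len(n_ru),
    res_ru2 = ru2_start + seq_len(n_ru) - 1L
  )

  truth <- structure(list(
    spec = spec,
    symmetry = c2,
    correspondence = correspondence,
    asymmetry = swing,
    structure = x_struct
  ), class = "toy_truth")

  truth$swapped <- make_swapped_truth(spec, truth)

  # exact transport-domain motion between original and swapped truth
  xs <- suppressWarnings(select_residues(x_struct, domains$transport))
  ys <- suppressWarnings(select_residues(truth$swapped, domains$transport))
  fit <- superpose(ca_coords(xs), ca_coords(ys))
  truth$transport_motion <- fit$transform
  truth$transport_motion_rmsd <- fit$rmsd
  truth$motion <- decompose_transform(fit$transform, membrane_frame(),
                                      colMeans(ca_coords(xs)))

  list(structure = x_struct, truth = truth, repeats = repeats,
       domains = domains)
}

#' Ground-truth swapped conformation of a toy transporter
#'
#' Returns the structure in which RU1 adopts RU2's conformation and vice
#' versa - the asymmetry-exchange product the repeat-swap pipeline should
#' reconstruct. Each repeat residue takes the coordinates of its partner
#' residue mapped back through the two-fold symmetry operation; peripheral
#' and connector residues map through the symmetry operation directly.
#'
#' @param spec The [toy_spec()] the truth was generated from.
#' @param truth The `toy_truth` from [make_toy_transporter()].
#' @return An atom tibble with the same numbering as the original.
#' @export
make_swapped_truth <- function(spec, truth) {
  stopifnot(inherits(truth, "toy_truth"))
  if (!identical(unclass(spec), unclass(truth$spec))) {
    abort("spec does not match the spec the truth was generated from")
  }
  x <- truth$structure
  c2 <- truth$symmetry
  co <- truth$correspondence
  partner <- integer(max(x$res_seq))
  partner[co$res_ru1] <- co$res_ru2
  partner[co$res_ru2] <- co$res_ru1
  y <- x
  xc <- apply_transform(x, c2)
  for (r in unique(x$res_seq)) {
    src <- if (partner[r] > 0) partner[r] else r
    yi <- which(y$res_seq == r)
    si <- which(x$res_seq == src)
    # atom composition is identical between partners by construction
    y[yi, c("x", "y", "z")] <- xc[si, c("x", "y", "z")]
  }
  attr(y, "title") <- "synthetic toy transporter, swapped conformation (ground truth)"
  attr(y, "provenance") <- paste0("make_swapped_truth(seed=", spec$seed, ")")
  y
}

#' @export
print.toy_spec <- function(x, ...) {
  cat(sprintf("<toy_spec> %d helices/repeat x %d res, asymmetry %.1f deg / %.1f A, %d peripheral, noise %.2f A, seed %d\n",
              x$helices_per_repeat, x$helix_length, x$asymmetry_angle_deg,
              x$asymmetry_shift_A, x$peripheral_helices, x$noise_A, x$seed))
  invisible(x)
}

#' @export
print.toy_truth <- function(x, ...) {
  cat("<toy_truth> symmetry 180 deg about in-plane axis;",
      nrow(x$correspondence), "corresponding residue pairs\n")
  invisible(x)
}
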