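#' Pairwise (gapped) alignment container
#'
#' Holds a gapped alignment of two residue sequences together with the list
#' of aligned residue pairs in author numbering. Degapping the two rows
#' reproduces the input sequences, and the pair list is strictly increasing
#' in both coordinates.
#'
#' @param gapped1,gapped2 Equal-length strings over the amino-acid alphabet
#'   plus `-`.
#' @param pairs Tibble with columns `res_seq1`, `res_seq2` (author numbers
#'   of aligned residues).
#' @return An object of class `pairwise_alignment`.
#' @export
pairwise_alignment <- function(gapped1, gapped2, pairs) {
  if (nchar(gapped1) != nchar(gapped2)) {
    abort("gapped sequences must have equal lengths")
  }
  pairs <- as_tibble(pairs)
  if (nrow(pairs) > 1) {
    if (any(diff(pairs$res_seq1) <= 0) || any(diff(pairs$res_seq2) <= 0)) {
      abort("pair list must be strictly increasing in both coordinates")
    }
  }
  structure(list(gapped1 = gapped1, gapped2 = gapped2, pairs = pairs),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> ", nrow(x$pairs), " aligned pairs, ",
      nchar(x$gapped1), " columns\n", sep = "")
  invisible(x)
}

# transpose: swap the roles of the two sequences
transpose_alignment <- function(aln) {
  pairwise_alignment(aln$gapped2, aln$gapped1,
                     tibble(res_seq1 = aln$pairs$res_seq2,
                            res_seq2 = aln$pairs$res_seq1))
}

# Needleman-Wunsch over an arbitrary similarity matrix with affine gaps
# (open cost, zero extension). Returns the aligned index pairs (i, j).
nw_pairs <- function(S, gap_open = 0.6) {
  n <- nrow(S)
  m <- ncol(S)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1) # gap in seq2 (consumes i)
  Iy <- matrix(NEG, n + 1, m + 1) # gap in seq1 (consumes j)
  M[1, 1] <- 0
  Ix[1, 1] <- -gap_open
  Iy[1, 1] <- -gap_open
  for (i in 2:(n + 1)) Ix[i, 1] <- -gap_open
  for (j in 2:(m + 1)) Iy[1, j] <- -gap_open
  tb <- matrix(0L, n + 1, m + 1) # 1 diag, 2 up (Ix), 3 left (Iy)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      best_prev <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      M[i, j] <- S[i - 1, j - 1] + best_prev
      Ix[i, j] <- max(M[i - 1, j] - gap_open, Ix[i - 1, j])
      Iy[i, j] <- max(M[i, j - 1] - gap_open, Iy[i, j - 1])
    }
  }
  # traceback from the best terminal state
  i <- n + 1
  j <- m + 1
  state <- which.max(c(M[i, j], Ix[i, j], Iy[i, j]))
  pi_ <- integer(0)
  pj <- integer(0)
  while (i > 1 || j > 1) {
    if (state == 1 && i > 1 && j > 1) {
      pi_ <- c(i - 1L, pi_)
      pj <- c(j - 1L, pj)
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      i <- i - 1L
      j <- j - 1L
      state <- which.max(prev)
    } else if (state == 2 && i > 1) {
      up_open <- M[i - 1, j] - gap_open
      state <- if (up_open >= Ix[i - 1, j]) 1L else 2L
      i <- i - 1L
    } else if (state == 3 && j > 1) {
      left_open <- M[i, j - 1] - gap_open
      state <- if (left_open >= Iy[i, j - 1]) 1L else 3L
      j <- j - 1L
    } else if (i > 1) {
      state <- 2L
    } else {
      state <- 3L
    }
  }
  cbind(i = pi_, j = pj)
}

# build gapped strings from sequences and an aligned index-pair matrix
gapped_from_pairs <- function(seq1, seq2, ip) {
  g1 <- character(0)
  g2 <- character(0)
  i <- 1L
  j <- 1L
  emit <- function(a, b) {
    g1 <<- c(g1, a)
    g2 <<- c(g2, b)
  }
  for (k in seq_len(nrow(ip) + 1L)) {
    ti <- if (k <= nrow(ip)) ip[k, 1] else length(seq1) + 1L
    tj <- if (k <= nrow(ip)) ip[k, 2] else length(seq2) + 1L
    while (i < ti) {
      emit(seq1[i], "-")
      i <- i + 1L
    }
    while (j < tj) {
      emit("-", seq2[j])
      j <- j + 1L
    }
    if (k <= nrow(ip)) {
      emit(seq1[i], seq2[j])
      i <- i + 1L
      j <- j + 1L
    }
  }
  list(g1 = paste(g1, collapse = ""), g2 = paste(g2, collapse = ""))
}

#' Sequence-independent structural alignment of two repeat units
#'
#' Aligns two repeat fragments by iterative dynamic programming over
#' inter-CA distance scores with superposition refinement (the TM-align
#' idea): starting from gapless seed correspondences, the current pair list
#' is used for a Kabsch fit, a TM-score local similarity matrix
#' `1/(1 + (d_ij/d0)^2)` is computed, and a new pair list extracted by
#' gapped dynamic programming; iteration stops when the pair list is stable
#' or after `max_iter` rounds (the best-scoring iteration is returned, with
#' a warning on non-convergence).
#'
#' @param ru1,ru2 Atom tibbles of the two repeat units (>= 10 residues
#'   each).
#' @param max_iter Maximum refinement iterations per seed.
#' @param gap_open Gap-opening penalty on the TM-score local term
#'   (extension is free).
#' @return A list of class `repeat_alignment`: `alignment` (a
#'   [pairwise_alignment()] in author numbering), `transform` (the
#'   `rigid_transform` superposing RU1 onto RU2 over the aligned pairs),
#'   and `tm` (TM-score normalised by the shorter repeat).
#' @export
align_repeats <- function(ru1, ru2, max_iter = 30, gap_open = 0.6) {
  c1 <- ca_coords(ru1)
  c2 <- ca_coords(ru2)
  n1 <- nrow(c1)
  n2 <- nrow(c2)
  if (n1 < 10 || n2 < 10) abort("each repeat must have at least 10 residues")
  l_min <- min(n1, n2)
  d0 <- tm_d0(l_min)

  seq1 <- aa_one(ru1$res_name[ru1$name == "CA" & !ru1$is_hetatm])
  seq2 <- aa_one(ru2$res_name[ru2$name == "CA" & !ru2$is_hetatm])

  score_pairs <- function(ip) {
    # TM-score-like sum over aligned pairs after fitting on them
    if (nrow(ip) < 3) return(-Inf)
    tf <- tryCatch(kabsch(c1[ip[, 1], , drop = FALSE], c2[ip[, 2], , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(tf)) return(-Inf)
    d2 <- rowSums((apply_transform(c1[ip[, 1], , drop = FALSE], tf) -
                     c2[ip[, 2], , drop = FALSE])^2)
    sum(1 / (1 + d2 / d0^2)) / l_min
  }

  # gapless seeds at a few offsets
  offsets <- unique(c(0L, -3L, 3L, -7L, 7L, n2 - n1))
  seeds <- list()
  for (off in offsets) {
    i <- seq_len(n1)
    j <- i + off
    ok <- j >= 1 & j <= n2
    if (sum(ok) >= 10) seeds[[length(seeds) + 1]] <- cbind(i = i[ok], j = j[ok])
  }

  best <- list(score = -Inf, ip = NULL, converged = FALSE)
  for (seed in seeds) {
    ip <- seed
    seen_stable <- FALSE
    for (iter in seq_len(max_iter)) {
      tf <- tryCatch(kabsch(c1[ip[, 1], , drop = FALSE], c2[ip[, 2], , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(tf)) break
      ft <- apply_transform(c1, tf)
      D2 <- outer(rowSums(ft^2), rowSums(c2^2), "+") - 2 * ft %*% t(c2)
      S <- 1 / (1 + pmax(D2, 0) / d0^2)
      new_ip <- nw_pairs(S, gap_open)
      sc <- score_pairs(new_ip)
      if (sc > best$score) {
        best <- list(score = sc, ip = new_ip, converged = FALSE)
      }
      if (nrow(new_ip) == nrow(ip) && all(new_ip == ip)) {
        seen_stable <- TRUE
        break
      }
      ip <- new_ip
    }
    if (seen_stable && best$score == score_pairs(ip)) best$converged <- TRUE
  }
  if (is.null(best$ip)) abort("structural alignment failed (degenerate input)")
  if (!best$converged) {
    warn("repeat alignment did not converge; returning best-scoring iteration")
  }

  ip <- best$ip
  tf <- kabsch(c1[ip[, 1], , drop = FALSE], c2[ip[, 2], , drop = FALSE])
  tm <- tm_score(apply_transform(c1[ip[, 1], , drop = FALSE], tf),
                 c2[ip[, 2], , drop = FALSE], l_norm = l_min)
  g <- gapped_from_pairs(seq1, seq2, ip)
  aln <- pairwise_alignment(
    g$g1, g$g2,
    tibble(res_seq1 = attr(c1, "res_seq")[ip[, 1]],
           res_seq2 = attr(c2, "res_seq")[ip[, 2]])
  )
  structure(list(alignment = aln, transform = tf, tm = as.numeric(tm)),
            class = "repeat_alignment")
}

#' @export
print.repeat_alignment <- function(x, ...) {
  cat(sprintf("<repeat_alignment> %d pairs, TM-score %.3f\n",
              nrow(x$alignment$pairs), x$tm))
  invisible(x)
}
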