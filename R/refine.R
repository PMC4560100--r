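#' Refine a swap alignment against template secondary structure
#'
#' Relocates gap openings that fall inside helical runs of the template:
#' a gap opened inside an 'H' run is moved to the nearest non-helix column
#' (ties broken toward the N-terminal side), preserving the number of
#' aligned pairs. Helix assignments come from DSSP output for the known
#' structure ([read_dssp()]) or from the CA-geometry fallback
#' ([assign_ss()]).
#'
#' If per-residue conservation scores are supplied, highly conserved
#' template residues (top quartile) left unaligned by the alignment are
#' reported as advisory diagnostics (attribute `diagnostics`), mirroring
#' the human-in-the-loop conservation check; nothing is auto-fixed.
#'
#' @param aln A [build_swap_alignment()] result.
#' @param ss_template Per-residue secondary-structure string for the
#'   template residues (template order; `H` marks helix), same length as
#'   the degapped template sequence.
#' @param conservation Optional numeric vector of per-residue conservation
#'   scores for the template residues (higher = more conserved).
#' @return The refined `swap_alignment` (same class), with attribute
#'   `n_moved` (gap runs relocated) and, when conservation was given,
#'   attribute `diagnostics`.
#' @export
refine_alignment <- function(aln, ss_template, conservation = NULL) {
  tg <- strsplit(aln$target_gapped, "")[[1]]
  tp <- strsplit(aln$template_gapped, "")[[1]]
  nres_tp <- sum(tp != "-")
  ss <- strsplit(ss_template, "")[[1]]
  if (length(ss) != nres_tp) {
    abort(paste0("secondary-structure string length (", length(ss),
                 ") does not match template residue count (", nres_tp, ")"))
  }
  # helix flag per column, from the template residue occupying the column;
  # template-gap columns take the flag of the run they interrupt
  col_res <- cumsum(tp != "-")
  col_res[col_res == 0] <- 1L
  helix_col <- ss[col_res] == "H"

  gap_runs <- function(v) {
    r <- rle(v == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(start = starts[r$values], end = ends[r$values])
  }

  move_run <- function(row, other, run, to_start) {
    # slide the gap run so it opens at to_start; the displaced characters
    # of `row` shift over the vacated columns. Only legal when the other
    # row is gapless over the affected span (pair count preserved).
    a <- run[1]
    b <- run[2]
    len <- b - a + 1L
    if (to_start < a) {
      span <- to_start:(a - 1L)
      if (any(other[span] == "-")) return(NULL)
      row[(to_start + len):(b)] <- row[span]
      row[to_start:(to_start + len - 1L)] <- "-"
    } else {
      span <- (b + 1L):(to_start + len - 1L)
      if (max(span) > length(row) || any(other[span] == "-")) return(NULL)
      row[a:(a + length(span) - 1L)] <- row[span]
      row[(to_start):(to_start + len - 1L)] <- "-"
    }
    row
  }

  n_moved <- 0L
  for (which_row in c("target", "template")) {
    row <- if (which_row == "target") tg else tp
    other <- if (which_row == "target") tp else tg
    runs <- gap_runs(row)
    if (nrow(runs) == 0) next
    for (k in seq_len(nrow(runs))) {
      a <- runs[k, 1]
      if (!helix_col[a]) next
      ncol_ <- length(row)
      # nearest non-helix opening column; tie -> N-terminal side
      cand <- which(!helix_col)
      if (length(cand) == 0) next
      dist_ <- abs(cand - a)
      cand <- cand[order(dist_, cand)]
      for (to in cand) {
        if (to == a) break
        moved <- move_run(row, other, runs[k, ], to)
        if (!is.null(moved)) {
          row <- moved
          n_moved <- n_moved + 1L
          break
        }
      }
    }
    if (which_row == "target") tg <- row else tp <- row
  }

  out <- rebuild_swap_alignment(aln, tg, tp)
  attr(out, "n_moved") <- n_moved
  if (!is.null(conservation)) {
    if (length(conservation) != nres_tp) {
      abort("conservation vector length does not match template residue count")
    }
    thr <- stats::quantile(conservation, 0.75, names = FALSE)
    tp2 <- strsplit(out$template_gapped, "")[[1]]
    tg2 <- strsplit(out$target_gapped, "")[[1]]
    resi <- cumsum(tp2 != "-")
    unal <- tp2 != "-" & tg2 == "-"
    flagged <- unique(resi[unal][conservation[resi[unal]] >= thr])
    attr(out, "diagnostics") <- tibble(
      template_pos = flagged,
      template_res_seq = out$template_res$res_seq[flagged],
      conservation = conservation[flagged],
      note = "highly conserved template residue unaligned in target"
    )
  }
  out
}

# reconstitute block annotations and mapping after editing gapped rows
rebuild_swap_alignment <- function(aln, tg, tp) {
  stopifnot(sum(tg != "-") == nrow(aln$target_res),
            sum(tp != "-") == nrow(aln$template_res))
  ti <- cumsum(tg != "-")
  pi_ <- cumsum(tp != "-")
  aligned <- tg != "-" & tp != "-"
  mapping <- tibble(
    target_chain = aln$target_res$chain_id[ti[aligned]],
    target_res_seq = aln$target_res$res_seq[ti[aligned]],
    template_chain = aln$template_res$chain_id[pi_[aligned]],
    template_res_seq = aln$template_res$res_seq[pi_[aligned]]
  )
  structure(list(
    target_gapped = paste(tg, collapse = ""),
    template_gapped = paste(tp, collapse = ""),
    blocks = aln$blocks,
    target_res = aln$target_res,
    template_res = aln$template_res,
    mapping = mapping
  ), class = "swap_alignment")
}

#' CA-geometry secondary-structure fallback
#'
#' Assigns helix ('H') versus coil ('C') from the CA trace alone: residue
#' windows where the i to i+3 CA distance stays at 5.1 +/- 0.6 Angstrom
#' over at least 4 consecutive window positions are called helical. A
#' coarse stand-in for DSSP when no assignment file is available.
#'
#' @param s An atom tibble.
#' @return A tibble `(chain_id, res_seq, ss)` per polymer residue.
#' @export
assign_ss <- function(s) {
  ca <- ca_coords(s)
  n <- nrow(ca)
  ss <- rep("C", n)
  if (n >= 7) {
    d3 <- sqrt(rowSums((ca[1:(n - 3), , drop = FALSE] -
                          ca[4:n, , drop = FALSE])^2))
    flag <- abs(d3 - 5.1) <= 0.6
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= 4)) {
      ss[starts[k]:(ends[k] + 3L)] <- "H"
    }
  }
  tibble(chain_id = attr(ca, "chain_id"), res_seq = attr(ca, "res_seq"), ss = ss)
}

#' Read a DSSP output file
#'
#' Parses the classic DSSP format (the residue block following the
#' `#  RESIDUE AA STRUCTURE` header line). Eight-state assignments are
#' retained in `ss_raw`; `ss` collapses them to helix (`H` for H/G/I),
#' strand (`E` for E/B) and coil (`C`).
#'
#' @param path Path to a DSSP file.
#' @return A tibble `(chain_id, res_seq, aa, ss_raw, ss)`.
#' @export
read_dssp <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) abort("not a DSSP file (no residue header)")
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  keep <- aa != "!" # chain breaks
  body <- body[keep]
  rs <- suppressWarnings(as.integer(trimws(substr(body, 6, 10))))
  raw <- substr(body, 17, 17)
  simple <- ifelse(raw %in% c("H", "G", "I"), "H",
                   ifelse(raw %in% c("E", "B"), "E", "C"))
  tibble(
    chain_id = substr(body, 12, 12),
    res_seq = rs,
    aa = aa[keep],
    ss_raw = ifelse(raw == " ", "C", raw),
    ss = simple
  )
}
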