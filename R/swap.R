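#' Build the duplicated (swapped) full-length alignment
#'
#' Constructs the target-template alignment used for repeat-swap modeling by
#' duplicating the repeat-repeat alignment: the target's RU1 residues are
#' aligned to the template's RU2 residues, the target's RU2 residues to the
#' template's RU1 residues (transposed pair list), peripheral segments are
#' aligned to themselves gaplessly, and linker residues belonging to no
#' block become target-only columns (all-gap template). The template is the
#' input structure with the order of the repeats reversed.
#'
#' @param s Atom tibble of the known structure (the template's source; also
#'   provides the full-length target sequence).
#' @param repeats A [repeat_definition()].
#' @param pair_aln A [pairwise_alignment()] of RU1 vs RU2 in author
#'   numbering (e.g. from [align_repeats()]).
#' @return An object of class `swap_alignment`: gapped `target_gapped` and
#'   `template_gapped` strings, a `blocks` tibble annotating column spans
#'   (`kind` one of `ru1_to_ru2`, `ru2_to_ru1`, `peripheral`, `linker`),
#'   `target_res` and `template_res` residue tables (template in swapped
#'   file order), and a `mapping` tibble of aligned residue pairs.
#' @export
build_swap_alignment <- function(s, repeats, pair_aln) {
  res <- residue_table(s)
  res <- res[!res$is_hetatm, , drop = FALSE]
  if (nrow(res) == 0) abort("structure has no polymer residues")
  cls <- rep("linker", nrow(res))
  cls[in_ranges(res$chain_id, res$res_seq, repeats$ru1)] <- "ru1"
  cls[in_ranges(res$chain_id, res$res_seq, repeats$ru2)] <- "ru2"
  cls[in_ranges(res$chain_id, res$res_seq, repeats$peripheral)] <- "peripheral"
  if (!any(cls == "ru1") || !any(cls == "ru2")) {
    abort("repeat ranges are absent from the structure")
  }
  pr <- pair_aln$pairs
  r1_all <- res$res_seq[cls == "ru1"]
  r2_all <- res$res_seq[cls == "ru2"]
  if (!all(pr$res_seq1 %in% r1_all) || !all(pr$res_seq2 %in% r2_all)) {
    abort("pair list references residues outside the repeat ranges")
  }

  # contiguous target blocks
  run_id <- cumsum(c(1L, as.integer(cls[-1] != cls[-length(cls)])))
  blocks <- split(seq_len(nrow(res)), run_id)

  # distribute template-side repeat residues monotonically over the target
  # blocks of the complementary repeat
  cursor2 <- 0L # consumed prefix of r2_all (template side of ru1 blocks)
  cursor1 <- 0L # consumed prefix of r1_all (template side of ru2 blocks)
  last_ru1_block <- max(c(0L, which(vapply(blocks, function(ii) cls[ii[1]] == "ru1", TRUE))))
  last_ru2_block <- max(c(0L, which(vapply(blocks, function(ii) cls[ii[1]] == "ru2", TRUE))))

  tg <- character(0)
  tp <- character(0)
  block_rows <- list()
  template_res <- list()
  mapping <- list()
  col <- 0L

  add_block <- function(kind, tcols_target, tcols_template, pairs_ij) {
    # tcols_target / tcols_template: row indices into res (target) and a
    # residue table (template side); pairs_ij: matrix of (target pos within
    # block, template pos within block)
    seq_t <- res$aa[tcols_target]
    seq_p <- tcols_template$aa
    g <- gapped_from_pairs(seq_t, seq_p, pairs_ij)
    ncol_b <- nchar(g$g1)
    tg <<- c(tg, g$g1)
    tp <<- c(tp, g$g2)
    block_rows[[length(block_rows) + 1]] <<- tibble(
      kind = kind, col_start = col + 1L, col_end = col + ncol_b
    )
    col <<- col + ncol_b
    template_res[[length(template_res) + 1]] <<- tcols_template
    if (nrow(pairs_ij) > 0) {
      mapping[[length(mapping) + 1]] <<- tibble(
        target_chain = res$chain_id[tcols_target[pairs_ij[, 1]]],
        target_res_seq = res$res_seq[tcols_target[pairs_ij[, 1]]],
        template_chain = tcols_template$chain_id[pairs_ij[, 2]],
        template_res_seq = tcols_template$res_seq[pairs_ij[, 2]]
      )
    }
  }

  res_sub <- function(rs) {
    i <- match(rs, res$res_seq)
    tibble(chain_id = res$chain_id[i], res_seq = res$res_seq[i], aa = res$aa[i])
  }

  for (b in seq_along(blocks)) {
    ii <- blocks[[b]]
    kind <- cls[ii[1]]
    if (kind == "peripheral") {
      n <- length(ii)
      add_block("peripheral", ii, res_sub(res$res_seq[ii]),
                cbind(seq_len(n), seq_len(n)))
    } else if (kind == "linker") {
      add_block("linker", ii,
                tibble(chain_id = character(), res_seq = integer(), aa = character()),
                cbind(integer(0), integer(0)))
    } else if (kind == "ru1") {
      in_block <- pr$res_seq1 %in% res$res_seq[ii]
      hi <- if (any(in_block)) match(max(pr$res_seq2[in_block]), r2_all) else cursor2
      if (b == last_ru1_block) hi <- length(r2_all)
      take2 <- if (hi > cursor2) r2_all[(cursor2 + 1L):hi] else integer(0)
      tmpl <- res_sub(take2)
      pij <- cbind(match(pr$res_seq1[in_block], res$res_seq[ii]),
                   match(pr$res_seq2[in_block], take2))
      pij <- pij[stats::complete.cases(pij), , drop = FALSE]
      add_block("ru1_to_ru2", ii, tmpl, pij)
      cursor2 <- hi
    } else { # ru2 block: template side is RU1 via the transposed pairs
      in_block <- pr$res_seq2 %in% res$res_seq[ii]
      hi <- if (any(in_block)) match(max(pr$res_seq1[in_block]), r1_all) else cursor1
      if (b == last_ru2_block) hi <- length(r1_all)
      take1 <- if (hi > cursor1) r1_all[(cursor1 + 1L):hi] else integer(0)
      tmpl <- res_sub(take1)
      pij <- cbind(match(pr$res_seq2[in_block], res$res_seq[ii]),
                   match(pr$res_seq1[in_block], take1))
      pij <- pij[stats::complete.cases(pij), , drop = FALSE]
      add_block("ru2_to_ru1", ii, tmpl, pij)
      cursor1 <- hi
    }
  }

  structure(list(
    target_gapped = paste(tg, collapse = ""),
    template_gapped = paste(tp, collapse = ""),
    blocks = bind_rows(block_rows),
    target_res = tibble(chain_id = res$chain_id, res_seq = res$res_seq,
                        aa = res$aa, class = cls),
    template_res = bind_rows(template_res),
    mapping = bind_rows(mapping)
  ), class = "swap_alignment")
}

#' @export
print.swap_alignment <- function(x, ...) {
  cat("<swap_alignment> ", nchar(x$target_gapped), " columns, ",
      nrow(x$mapping), " aligned pairs\n", sep = "")
  k <- table(x$blocks$kind)
  cat("  blocks:", paste(names(k), k, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Assemble the swapped template coordinate file
#'
#' Reorders the repeats of the known structure (RU2 before RU1, peripheral
#' segments at their swapped sequence positions) and renumbers residues
#' consecutively, producing the template for repeat-swap modeling. Because
#' the swapped model is upside-down with respect to the template, peripheral
#' fragments must be reoriented: when `initial_model` is supplied, the known
#' structure is superposed onto it via an RU1-onto-RU1 CA fit and the
#' resulting transform is applied to the peripheral fragments before
#' insertion.
#'
#' Linker residues belonging to no block, waters and other HETATM groups
#' are omitted from the template.
#'
#' @param xray Atom tibble of the known structure.
#' @param repeats A [repeat_definition()].
#' @param initial_model Optional preliminary swapped model used to reorient
#'   peripheral fragments.
#' @param aln Optional [build_swap_alignment()] result; when supplied the
#'   template residue order follows the alignment exactly (required for a
#'   split repeat unit).
#' @param renumber_from First residue number of the renumbered template.
#' @return A list of class `swapped_template`: `structure` (renumbered atom
#'   tibble), `map` (tibble `old_chain`, `old_res_seq`, `new_res_seq`), and
#'   `order` (old residue numbers in template order).
#' @export
assemble_swapped_template <- function(xray, repeats, initial_model = NULL,
                                      aln = NULL, renumber_from = 1L) {
  res <- residue_table(xray)
  res <- res[!res$is_hetatm, , drop = FALSE]
  cls <- rep("linker", nrow(res))
  cls[in_ranges(res$chain_id, res$res_seq, repeats$ru1)] <- "ru1"
  cls[in_ranges(res$chain_id, res$res_seq, repeats$ru2)] <- "ru2"
  cls[in_ranges(res$chain_id, res$res_seq, repeats$peripheral)] <- "peripheral"
  if (!any(cls == "ru1") || !any(cls == "ru2")) {
    abort("repeat ranges are absent from the structure")
  }

  if (!is.null(aln)) {
    ord_res <- aln$template_res$res_seq
  } else {
    # swapped order: walk target blocks; the first RU1 block takes all of
    # RU2, the first RU2 block takes all of RU1, peripherals keep position
    run_id <- cumsum(c(1L, as.integer(cls[-1] != cls[-length(cls)])))
    ord_res <- integer(0)
    done1 <- FALSE
    done2 <- FALSE
    for (ii in split(seq_len(nrow(res)), run_id)) {
      kind <- cls[ii[1]]
      if (kind == "peripheral") {
        ord_res <- c(ord_res, res$res_seq[ii])
      } else if (kind == "ru1" && !done2) {
        ord_res <- c(ord_res, res$res_seq[cls == "ru2"])
        done2 <- TRUE
      } else if (kind == "ru2" && !done1) {
        ord_res <- c(ord_res, res$res_seq[cls == "ru1"])
        done1 <- TRUE
      }
    }
  }

  s <- xray[!xray$is_hetatm, , drop = FALSE]
  periph_res <- res$res_seq[cls == "peripheral"]
  if (length(periph_res) > 0 && !is.null(initial_model)) {
    ru1_sel <- select_residues(s, repeats$ru1)
    cx <- ca_coords(ru1_sel)
    cmld <- ca_coords(initial_model)
    shared <- intersect(rownames(cx), rownames(cmld))
    if (length(shared) < 3) abort("too few shared RU1 residues for peripheral reorientation")
    fit <- superpose(cx[match(shared, rownames(cx)), , drop = FALSE],
                     cmld[match(shared, rownames(cmld)), , drop = FALSE])
    pa <- s$res_seq %in% periph_res
    s[pa, c("x", "y", "z")] <- apply_transform(s[pa, , drop = FALSE],
                                               fit$transform)[, c("x", "y", "z")]
  }

  pieces <- lapply(ord_res, function(r) s[s$res_seq == r, , drop = FALSE])
  out <- bind_rows(pieces)
  key <- paste(out$chain_id, out$res_seq, out$i_code, sep = "\r")
  new_seq <- renumber_from + match(key, unique(key)) - 1L
  first <- !duplicated(key)
  map <- tibble(old_chain = out$chain_id[first], old_res_seq = out$res_seq[first],
                new_res_seq = new_seq[first])
  out$res_seq <- new_seq
  out$i_code <- " "
  attr(out, "title") <- attr(xray, "title")
  attr(out, "provenance") <- paste0(
    attr(xray, "provenance") %||% "", "; swapped template (RU2 before RU1), ",
    if (!is.null(initial_model)) "peripherals reoriented via RU1 fit, " else "",
    "renumbered from ", renumber_from)
  structure(list(structure = out, map = map, order = ord_res),
            class = "swapped_template")
}

#' @export
print.swapped_template <- function(x, ...) {
  cat("<swapped_template> ", nrow(x$map), " residues, ",
      nrow(x$structure), " atoms\n", sep = "")
  invisible(x)
}
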