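#' Modeling configuration
#'
#' Iteration counts for the model-building stages: 200 models after each
#' alignment refinement round, 2000 models once intra-domain and ligand
#' restraints are applied (more sampling is needed for a model that
#' satisfies all restraints simultaneously).
#'
#' @param n_models_initial Models built per alignment-refinement round.
#' @param n_models_restrained Models built in the restrained stages.
#' @param include_ligands Whether the bundle includes ligand restraints.
#' @param random_seed Seed recorded in the driver skeleton.
#' @return A list of class `modeling_config`.
#' @export
modeling_config <- function(n_models_initial = 200L, n_models_restrained = 2000L,
                            include_ligands = TRUE, random_seed = 1L) {
  stopifnot(n_models_initial >= 1, n_models_restrained >= 1)
  structure(list(n_models_initial = as.integer(n_models_initial),
                 n_models_restrained = as.integer(n_models_restrained),
                 include_ligands = isTRUE(include_ligands),
                 random_seed = as.integer(random_seed)),
            class = "modeling_config")
}

#' Naive coordinate-transfer model builder
#'
#' Builds a backbone-only swapped model without any external modeling
#' engine: each aligned target residue receives the backbone (N, CA, C, O,
#' and CB when present) coordinates of its template partner; unaligned
#' target residues are placed by linear CA interpolation between the
#' flanking aligned anchors and flagged low-confidence via occupancy 0.
#' This makes the whole protocol and the downstream motion analysis
#' testable end to end; it is deliberately not a substitute for
#' restraint-based model building.
#'
#' @param template A [assemble_swapped_template()] result.
#' @param aln A [build_swap_alignment()] result consistent with the
#'   template.
#' @return An atom tibble of the model, on target numbering.
#' @export
build_naive_model <- function(template, aln) {
  stopifnot(inherits(template, "swapped_template"))
  ts <- template$structure
  # template sequence consistency: alignment template row vs template file
  tp_seq <- strsplit(gsub("-", "", aln$template_gapped), "")[[1]]
  file_res <- residue_table(ts)
  file_res <- file_res[!file_res$is_hetatm, , drop = FALSE]
  if (length(tp_seq) != nrow(file_res) || any(tp_seq != file_res$aa)) {
    bad <- which(tp_seq != file_res$aa[seq_along(tp_seq)])
    first_bad <- if (length(bad)) bad[1] else min(length(tp_seq), nrow(file_res)) + 1L
    gap_cols <- which(strsplit(aln$template_gapped, "")[[1]] != "-")
    abort(paste0("alignment/template sequence mismatch at alignment column ",
                 gap_cols[min(first_bad, length(gap_cols))]))
  }

  # template residue: old numbering -> renumbered structure rows
  old2new <- setNames(template$map$new_res_seq,
                      paste(template$map$old_chain, template$map$old_res_seq))

  tgt <- aln$target_res
  m <- aln$mapping
  mk <- match(paste(tgt$chain_id, tgt$res_seq),
              paste(m$target_chain, m$target_res_seq))
  rows <- vector("list", nrow(tgt))
  anchor_ca <- matrix(NA_real_, nrow(tgt), 3)
  for (i in seq_len(nrow(tgt))) {
    if (is.na(mk[i])) next
    new_seq <- old2new[paste(m$template_chain[mk[i]], m$template_res_seq[mk[i]])]
    res_atoms <- ts[ts$res_seq == new_seq, , drop = FALSE]
    bb <- res_atoms[res_atoms$name %in% c("N", "CA", "C", "O", "CB"), , drop = FALSE]
    if (tgt$aa[i] == "G") bb <- bb[bb$name != "CB", , drop = FALSE]
    if (nrow(bb) == 0) next
    rows[[i]] <- tibble(
      serial = 0L, name = bb$name, altloc = " ",
      res_name = AA1TO3[tgt$aa[i]] %||% "UNK",
      chain_id = tgt$chain_id[i], res_seq = tgt$res_seq[i], i_code = " ",
      x = bb$x, y = bb$y, z = bb$z, occupancy = 1,
      element = bb$element, is_hetatm = FALSE
    )
    rows[[i]]$res_name[is.na(rows[[i]]$res_name)] <- "UNK"
    ca <- bb[bb$name == "CA", , drop = FALSE]
    if (nrow(ca) == 1) anchor_ca[i, ] <- c(ca$x, ca$y, ca$z)
  }

  # interpolate unaligned residues between flanking anchors
  have <- which(!is.na(anchor_ca[, 1]))
  for (i in seq_len(nrow(tgt))) {
    if (!is.null(rows[[i]])) next
    prev <- max(c(have[have < i], -Inf))
    nxt <- min(c(have[have > i], Inf))
    if (is.infinite(prev) && is.infinite(nxt)) {
      abort("no aligned residues; cannot build a model")
    }
    if (is.infinite(prev)) {
      # leading tail: stack just beyond the first anchor
      pos <- anchor_ca[nxt, ] + (i - nxt) * c(0.38, 0, 0)
    } else if (is.infinite(nxt)) {
      pos <- anchor_ca[prev, ] + (i - prev) * c(0.38, 0, 0)
    } else {
      f <- (i - prev) / (nxt - prev)
      pos <- (1 - f) * anchor_ca[prev, ] + f * anchor_ca[nxt, ]
    }
    rows[[i]] <- tibble(
      serial = 0L, name = "CA", altloc = " ",
      res_name = AA1TO3[tgt$aa[i]] %||% "UNK",
      chain_id = tgt$chain_id[i], res_seq = tgt$res_seq[i], i_code = " ",
      x = pos[1], y = pos[2], z = pos[3], occupancy = 0,
      element = "C", is_hetatm = FALSE
    )
    rows[[i]]$res_name[is.na(rows[[i]]$res_name)] <- "UNK"
  }
  out <- bind_rows(rows)
  out$serial <- seq_len(nrow(out))
  attr(out, "title") <- "naive repeat-swap model (coordinate transfer)"
  attr(out, "provenance") <- "build_naive_model: backbone transfer from swapped template; occupancy 0 marks interpolated residues"
  out
}

#' Write / read PIR alignments (Modeller dialect)
#'
#' @param path File path.
#' @param entries A list of entries, each a list with `id`, `type`
#'   (`structureX` or `sequence`), `fields` (the colon-separated header
#'   remainder) and `seq` (gapped sequence, `*` appended on write).
#' @return `read_pir()`: a list of entries of the same shape.
#' @export
write_pir <- function(path, entries) {
  con <- file(path, "w")
  on.exit(close(con))
  for (e in entries) {
    writeLines(paste0(">P1;", e$id), con)
    writeLines(paste0(e$type, ":", e$fields), con)
    sq <- paste0(e$seq, "*")
    writeLines(substring(sq, seq(1, nchar(sq), 75),
                         pmin(seq(1, nchar(sq), 75) + 74, nchar(sq))), con)
  }
  invisible(path)
}

#' @rdname write_pir
#' @export
read_pir <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^>P1;", lines)
  if (length(starts) == 0) abort("no PIR entries found")
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    id <- sub("^>P1;", "", lines[starts[k]])
    hdr <- lines[starts[k] + 1L]
    type <- sub(":.*$", "", hdr)
    fields <- sub("^[^:]*:", "", hdr)
    seq <- paste(lines[(starts[k] + 2L):ends[k]], collapse = "")
    seq <- gsub("[[:space:]]", "", seq)
    if (!grepl("\\*$", seq)) abort(paste0("PIR entry ", id, " not terminated by '*'"))
    list(id = id, type = type, fields = fields, seq = sub("\\*$", "", seq))
  })
}

#' Emit a Modeller-ready input bundle
#'
#' Writes everything an external restraint-based modeling run needs:
#' the swapped template PDB, the PIR alignment (structureX entry for the
#' template, sequence entry for the target), the restraint table (TSV) with
#' a Modeller-syntax Gaussian restraint stanza, and a driver script
#' skeleton parameterised by the configuration. File names are
#' cross-referenced so the bundle is self-consistent (see
#' [validate_bundle()]).
#'
#' @param template A [assemble_swapped_template()] result.
#' @param aln A [build_swap_alignment()] result.
#' @param restraints Restraint tibble on model numbering (e.g. from
#'   [map_restraints()]); may be empty.
#' @param config A [modeling_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
emit_modeling_inputs <- function(template, aln, restraints,
                                 config = modeling_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p_pdb <- file.path(outdir, "swapped_template.pdb")
  p_pir <- file.path(outdir, "alignment.pir")
  p_tsv <- file.path(outdir, "restraints.tsv")
  p_rsr <- file.path(outdir, "restraints_modeller.py")
  p_drv <- file.path(outdir, "run_modeller.py")
  p_rdm <- file.path(outdir, "README.txt")

  write_pdb(template$structure, p_pdb)

  ts <- template$structure
  n_tres <- nrow(template$map)
  chain <- ts$chain_id[1]
  tgt_chain <- aln$target_res$chain_id[1]
  tgt_first <- aln$target_res$res_seq[1]
  tgt_last <- aln$target_res$res_seq[nrow(aln$target_res)]
  write_pir(p_pir, list(
    list(id = "swapped_template", type = "structureX",
         fields = paste0("swapped_template:", min(ts$res_seq), ":", chain, ":",
                         max(ts$res_seq), ":", chain, "::::"),
         seq = aln$template_gapped),
    list(id = "target", type = "sequence",
         fields = paste0("target:", tgt_first, ":", tgt_chain, ":", tgt_last,
                         ":", tgt_chain, "::::"),
         seq = aln$target_gapped)
  ))

  write_restraints(restraints, p_tsv)
  stanza <- sprintf(
    "rsr.add(forms.Gaussian(group=physical.xy_distance, feature=features.Distance(atoms['%s:%d:%s'], atoms['%s:%d:%s']), mean=%.4f, stdev=%.4f))",
    restraints$atom_a, restraints$res_a, restraints$chain_a,
    restraints$atom_b, restraints$res_b, restraints$chain_b,
    restraints$target_A, restraints$sigma_A)
  writeLines(c("# Gaussian distance restraints on model numbering",
               "# applied inside MyModel.special_restraints(); one line per restraint",
               stanza), p_rsr)

  drv <- c(
    "# Driver skeleton for restraint-based repeat-swap model building.",
    "# Requires Modeller (https://salilab.org); not executed by this package.",
    "from modeller import *",
    "from modeller.automodel import *",
    "",
    sprintf("env = environ(rand_seed=-%d)", abs(config$random_seed)),
    "env.io.atom_files_directory = ['.']",
    "",
    "class SwapModel(automodel):",
    "    def special_restraints(self, aln):",
    "        rsr = self.restraints",
    "        at = self.atoms",
    "        exec(open('restraints_modeller.py').read())",
    "",
    "a = SwapModel(env, alnfile='alignment.pir',",
    "              knowns='swapped_template', sequence='target')",
    "a.starting_model = 1",
    sprintf("a.ending_model = %d  # restrained stage", config$n_models_restrained),
    sprintf("# initial (unrestrained) rounds: %d models each", config$n_models_initial),
    "a.make()"
  )
  writeLines(drv, p_drv)

  writeLines(c(
    "Repeat-swap modeling input bundle",
    "---------------------------------",
    "swapped_template.pdb    swapped, renumbered template coordinates",
    "alignment.pir           target vs swapped-template alignment (PIR)",
    "restraints.tsv          Gaussian distance restraints (model numbering)",
    "restraints_modeller.py  the same restraints as a Modeller stanza",
    "run_modeller.py         driver skeleton (requires Modeller)",
    "",
    sprintf("models per refinement round: %d; restrained stage: %d",
            config$n_models_initial, config$n_models_restrained),
    "",
    "Select final models externally by MolPDF / ProQM / Procheck;",
    "restraint_score() in this package provides only a crude internal",
    "violation ranking."
  ), p_rdm)

  invisible(c(p_pdb, p_pir, p_tsv, p_rsr, p_drv, p_rdm))
}

#' Validate an emitted modeling bundle
#'
#' Re-reads every file of an [emit_modeling_inputs()] bundle and checks
#' cross-consistency: the PIR template entry degaps to the template PDB
#' sequence, the target entry degaps to the target sequence length, the
#' restraint stanza has one line per TSV restraint, and the driver
#' references the emitted file names.
#'
#' @param outdir Bundle directory.
#' @return A tibble of checks (`check`, `ok`); attribute `ok` is the
#'   conjunction.
#' @export
validate_bundle <- function(outdir) {
  checks <- list()
  add <- function(name, ok) checks[[length(checks) + 1]] <<- tibble(check = name, ok = ok)
  s <- read_pdb(file.path(outdir, "swapped_template.pdb"))
  pir <- read_pir(file.path(outdir, "alignment.pir"))
  ids <- vapply(pir, `[[`, "", "id")
  add("pir has template and target entries",
      all(c("swapped_template", "target") %in% ids))
  tmpl_seq <- gsub("-", "", pir[[which(ids == "swapped_template")]]$seq)
  file_seq <- paste(residue_table(s)$aa, collapse = "")
  add("template PIR degaps to template PDB sequence",
      identical(tmpl_seq, file_seq))
  tgt_seq <- gsub("-", "", pir[[which(ids == "target")]]$seq)
  add("gapped rows have equal length",
      nchar(pir[[1]]$seq) == nchar(pir[[2]]$seq))
  tsv <- utils::read.delim(file.path(outdir, "restraints.tsv"))
  stanza <- readLines(file.path(outdir, "restraints_modeller.py"))
  stanza <- grep("^rsr\\.add", stanza, value = TRUE)
  add("stanza line count equals restraint count", length(stanza) == nrow(tsv))
  drv <- readLines(file.path(outdir, "run_modeller.py"))
  add("driver references bundle files",
      any(grepl("alignment.pir", drv)) && any(grepl("swapped_template", drv)))
  out <- bind_rows(checks)
  attr(out, "ok") <- all(out$ok)
  if (!all(out$ok)) warn("bundle failed self-validation; see returned checks")
  out
}

#' One-call repeat-swap pipeline
#'
#' Runs the full protocol on a single structure: repeat structural
#' alignment, duplicated swap alignment, swapped-template assembly, a first
#' naive model, peripheral reorientation against that model, and the final
#' naive model.
#'
#' @param s Atom tibble of the known structure.
#' @param repeats A [repeat_definition()].
#' @param refine_ss Optional template secondary-structure string passed to
#'   [refine_alignment()].
#' @return A list with `model` (atom tibble), `alignment`
#'   (`swap_alignment`), `template` (`swapped_template`), and
#'   `repeat_alignment`.
#' @export
repeat_swap_model <- function(s, repeats, refine_ss = NULL) {
  ru1 <- suppressWarnings(select_residues(s, repeats$ru1))
  ru2 <- suppressWarnings(select_residues(s, repeats$ru2))
  ra <- align_repeats(ru1, ru2)
  aln <- build_swap_alignment(s, repeats, ra$alignment)
  if (!is.null(refine_ss)) aln <- refine_alignment(aln, refine_ss)
  tmpl0 <- assemble_swapped_template(s, repeats, aln = aln)
  model0 <- build_naive_model(tmpl0, aln)
  has_periph <- nrow(repeats$peripheral) > 0
  if (has_periph) {
    tmpl <- assemble_swapped_template(s, repeats, initial_model = model0,
                                      aln = aln)
    model <- build_naive_model(tmpl, aln)
  } else {
    tmpl <- tmpl0
    model <- model0
  }
  list(model = model, alignment = aln, template = tmpl, repeat_alignment = ra)
}
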