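#' Intra-domain CA-CA distance restraints
#'
#' Generates one Gaussian distance restraint for every unordered pair of CA
#' atoms strictly closer than `cutoff` within each domain taken
#' independently (cross-domain pairs are never restrained). Targets are the
#' distances observed in the input structure; these restraints preserve the
#' internal packing of the scaffold and transport domains during modeling.
#'
#' @param s Atom tibble of the known structure.
#' @param domains A [domain_definition()].
#' @param cutoff Distance cutoff in Angstrom (strict `<`; default 60).
#' @param sigma Gaussian standard deviation in Angstrom (default 0.1).
#' @return A restraint tibble with columns `group`, `chain_a`, `res_a`,
#'   `atom_a`, `chain_b`, `res_b`, `atom_b`, `target_A`, `sigma_A`, plus a
#'   `counts` attribute (restraints per group) and `n_missing_ca`
#'   (domain residues lacking a CA, skipped with a warning).
#' @examples
#' toy <- make_toy_transporter(toy_spec(seed = 1))
#' r <- intra_domain_restraints(toy$structure, toy$domains, cutoff = 20)
#' attr(r, "counts")
#' @export
intra_domain_restraints <- function(s, domains, cutoff = 60, sigma = 0.1) {
  stopifnot(inherits(domains, "domain_definition"))
  out <- list()
  n_missing <- 0L
  for (grp in c("scaffold", "transport")) {
    sel <- suppressWarnings(select_residues(s, domains[[grp]]))
    resid <- residue_table(sel)
    resid <- resid[!resid$is_hetatm, , drop = FALSE]
    ca <- sel[sel$name == "CA" & !sel$is_hetatm, , drop = FALSE]
    miss <- nrow(resid) - nrow(ca)
    if (miss > 0) {
      n_missing <- n_missing + miss
      warn(paste0(miss, " ", grp, " residue(s) lack a CA atom; skipped"))
    }
    n <- nrow(ca)
    if (n < 2) next
    D <- as.matrix(dist(cbind(ca$x, ca$y, ca$z)))
    hit <- which(upper.tri(D) & D < cutoff, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    out[[grp]] <- tibble(
      group = grp,
      chain_a = ca$chain_id[hit[, 1]], res_a = ca$res_seq[hit[, 1]], atom_a = "CA",
      chain_b = ca$chain_id[hit[, 2]], res_b = ca$res_seq[hit[, 2]], atom_b = "CA",
      target_A = D[hit], sigma_A = sigma
    )
  }
  r <- bind_rows(out)
  r <- dedupe_restraints(r)
  tab <- table(factor(r$group, levels = c("scaffold", "transport")))
  attr(r, "counts") <- setNames(as.integer(tab), names(tab))
  attr(r, "n_missing_ca") <- n_missing
  r
}

dedupe_restraints <- function(r) {
  if (nrow(r) == 0) return(r)
  a <- paste(r$chain_a, r$res_a, r$atom_a)
  b <- paste(r$chain_b, r$res_b, r$atom_b)
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  if (any(a == b)) abort("restraint between an atom and itself")
  r[!duplicated(paste(lo, hi)), , drop = FALSE]
}

#' Ligand-protein distance restraints
#'
#' Generates Gaussian restraints between every heavy (non-hydrogen) ligand
#' atom and every heavy protein atom strictly closer than `cutoff`
#' (5 Angstrom for the Glt_Ph aspartate/Na+ sites; 3.5 Angstrom for the
#' VcCNT uridine site). An explicit `named_pairs` table adds specific
#' protein partners regardless of distance - the named sodium-site mode -
#' and may include a crystallographic water (resolved to the water oxygen
#' nearest the ligand).
#'
#' @param s Atom tibble containing both protein and ligand records.
#' @param ligands Ligand selection: HETATM residue names (e.g.
#'   `c("ASP", "NA")`) or a tibble `(chain_id, res_seq)`.
#' @param cutoff Distance cutoff in Angstrom (strict `<`).
#' @param sigma Gaussian standard deviation in Angstrom.
#' @param named_pairs Optional tibble of protein partners with columns
#'   `chain_b`, `res_b`, `atom_b` (and optional `res_name_b`; rows with
#'   `res_b = NA` and `res_name_b = "HOH"` select the nearest water O).
#' @return A restraint tibble (columns as in
#'   [intra_domain_restraints()], `group = "ligand"`).
#' @export
ligand_restraints <- function(s, ligands, cutoff = 5, sigma = 0.1,
                              named_pairs = NULL) {
  if (is.data.frame(ligands)) {
    lig_idx <- paste(s$chain_id, s$res_seq) %in%
      paste(ligands$chain_id, ligands$res_seq)
  } else {
    lig_idx <- s$is_hetatm & s$res_name %in% ligands
  }
  if (!any(lig_idx)) abort("empty ligand selection")
  heavy <- !(toupper(s$element) %in% c("H", "D"))
  lig <- s[lig_idx & heavy, , drop = FALSE]
  prot <- s[!lig_idx & heavy & !s$is_hetatm, , drop = FALSE]
  lm <- cbind(lig$x, lig$y, lig$z)
  pm <- cbind(prot$x, prot$y, prot$z)
  D <- sqrt(pmax(outer(rowSums(lm^2), rowSums(pm^2), "+") - 2 * lm %*% t(pm), 0))
  hit <- which(D < cutoff, arr.ind = TRUE)
  r <- tibble(
    group = "ligand",
    chain_a = lig$chain_id[hit[, 1]], res_a = lig$res_seq[hit[, 1]],
    atom_a = lig$name[hit[, 1]],
    chain_b = prot$chain_id[hit[, 2]], res_b = prot$res_seq[hit[, 2]],
    atom_b = prot$name[hit[, 2]],
    target_A = D[hit], sigma_A = sigma
  )
  if (!is.null(named_pairs)) {
    waters <- s[s$is_hetatm & s$res_name == "HOH" & s$name == "O", , drop = FALSE]
    extra <- list()
    for (k in seq_len(nrow(named_pairs))) {
      np <- named_pairs[k, ]
      if (is.na(np$res_b) && identical(np$res_name_b %||% "", "HOH")) {
        if (nrow(waters) == 0) {
          warn("named water partner requested but no water present; skipped")
          next
        }
        dw <- outer(rowSums(cbind(waters$x, waters$y, waters$z)^2),
                    rowSums(lm^2), "+") -
          2 * cbind(waters$x, waters$y, waters$z) %*% t(lm)
        wi <- which(dw == min(dw), arr.ind = TRUE)[1, ]
        part <- waters[wi[1], , drop = FALSE]
        li <- lig[wi[2], , drop = FALSE]
      } else {
        cand <- s[s$chain_id == np$chain_b & s$res_seq == np$res_b &
                    s$name == np$atom_b, , drop = FALSE]
        if (nrow(cand) == 0) {
          warn(paste0("named partner ", np$chain_b, ":", np$res_b, ":",
                      np$atom_b, " not found; skipped"))
          next
        }
        if (!is.null(np$res_name_b) && !is.na(np$res_name_b) &&
            cand$res_name[1] != np$res_name_b) {
          warn(paste0("named partner ", np$chain_b, ":", np$res_b,
                      " is ", cand$res_name[1], ", expected ", np$res_name_b))
        }
        part <- cand[1, , drop = FALSE]
        dl <- rowSums(sweep(lm, 2, c(part$x, part$y, part$z))^2)
        li <- lig[which.min(dl), , drop = FALSE]
      }
      extra[[length(extra) + 1]] <- tibble(
        group = "ligand",
        chain_a = li$chain_id, res_a = li$res_seq, atom_a = li$name,
        chain_b = part$chain_id, res_b = part$res_seq, atom_b = part$name,
        target_A = sqrt(sum((c(li$x, li$y, li$z) - c(part$x, part$y, part$z))^2)),
        sigma_A = sigma
      )
    }
    r <- bind_rows(r, bind_rows(extra))
  }
  dedupe_restraints(r)
}

#' Map template restraints onto model numbering
#'
#' Restraints are measured on the template (known) structure but applied to
#' the model being built; this translates residue numbers through the
#' swap-alignment mapping (template residue to aligned target residue).
#' Restraints on residues left unaligned are dropped with a warning.
#'
#' @param r A restraint tibble.
#' @param aln A [build_swap_alignment()] result.
#' @return The mapped restraint tibble; attribute `n_dropped` counts
#'   unmappable restraints.
#' @export
map_restraints <- function(r, aln) {
  m <- aln$mapping
  key <- paste(m$template_chain, m$template_res_seq)
  ka <- match(paste(r$chain_a, r$res_a), key)
  kb <- match(paste(r$chain_b, r$res_b), key)
  ok <- !is.na(ka) & !is.na(kb)
  if (any(!ok)) {
    warn(paste0(sum(!ok), " restraint(s) reference unaligned residues; dropped"))
  }
  out <- r[ok, , drop = FALSE]
  out$chain_a <- m$target_chain[ka[ok]]
  out$res_a <- m$target_res_seq[ka[ok]]
  out$chain_b <- m$target_chain[kb[ok]]
  out$res_b <- m$target_res_seq[kb[ok]]
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Write restraints as TSV
#'
#' @param r A restraint tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_restraints <- function(r, path) {
  utils::write.table(
    r[, c("chain_a", "res_a", "atom_a", "chain_b", "res_b", "atom_b",
          "target_A", "sigma_A", "group")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sum-of-squares restraint violation score
#'
#' Internal ranking aid: the sum over restraints of
#' `((d_observed - target) / sigma)^2` evaluated on a structure. Restraints
#' whose atoms are absent are skipped (counted in attribute `n_skipped`).
#' This is package plumbing for ranking naive models, not a substitute for
#' established model-assessment tools.
#'
#' @param s Atom tibble (the model).
#' @param r Restraint tibble on the model's numbering.
#' @return Numeric score (0 = all restraints satisfied exactly).
#' @export
restraint_score <- function(s, r) {
  key <- paste(s$chain_id, s$res_seq, s$name)
  ia <- match(paste(r$chain_a, r$res_a, r$atom_a), key)
  ib <- match(paste(r$chain_b, r$res_b, r$atom_b), key)
  ok <- !is.na(ia) & !is.na(ib)
  d <- sqrt((s$x[ia[ok]] - s$x[ib[ok]])^2 + (s$y[ia[ok]] - s$y[ib[ok]])^2 +
              (s$z[ia[ok]] - s$z[ib[ok]])^2)
  out <- sum(((d - r$target_A[ok]) / r$sigma_A[ok])^2)
  attr(out, "n_skipped") <- sum(!ok)
  out
}
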