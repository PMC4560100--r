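# duplicated swap alignment, template assembly, alignment refinement

make_swap_inputs <- function(toy) {
  ru1 <- suppressWarnings(select_residues(toy$structure, toy$repeats$ru1))
  ru2 <- suppressWarnings(select_residues(toy$structure, toy$repeats$ru2))
  ra <- align_repeats(ru1, ru2)
  list(ra = ra, aln = build_swap_alignment(toy$structure, toy$repeats,
                                           ra$alignment))
}

test_that("a perfectly symmetric toy yields a gapless swap alignment", {
  toy <- symmetric_toy(1)
  aln <- make_swap_inputs(toy)$aln
  expect_false(grepl("-", aln$target_gapped, fixed = TRUE))
  expect_false(grepl("-", aln$template_gapped, fixed = TRUE))
  expect_equal(nchar(aln$target_gapped), nrow(aln$target_res))
  kinds <- aln$blocks$kind
  expect_equal(kinds[kinds != "peripheral"], c("ru1_to_ru2", "ru2_to_ru1"))
})

test_that("column count equals target length plus template-only gaps", {
  toy <- default_toy(3)
  aln <- make_swap_inputs(toy)$aln
  tg <- strsplit(aln$target_gapped, "")[[1]]
  expect_equal(length(tg), nrow(aln$target_res) + sum(tg == "-"))
  # degapping reproduces target and template sequences
  expect_equal(gsub("-", "", aln$target_gapped),
               paste(aln$target_res$aa, collapse = ""))
  expect_equal(gsub("-", "", aln$template_gapped),
               paste(aln$template_res$aa, collapse = ""))
})

test_that("repeat blocks pair target RU1 with template RU2 and vice versa", {
  toy <- default_toy(5)
  aln <- make_swap_inputs(toy)$aln
  m <- aln$mapping
  in1 <- swapsmith:::in_ranges(m$target_chain, m$target_res_seq, toy$repeats$ru1)
  in2 <- swapsmith:::in_ranges(m$target_chain, m$target_res_seq, toy$repeats$ru2)
  t_in1 <- swapsmith:::in_ranges(m$template_chain, m$template_res_seq, toy$repeats$ru1)
  t_in2 <- swapsmith:::in_ranges(m$template_chain, m$template_res_seq, toy$repeats$ru2)
  expect_true(all(t_in2[in1]))
  expect_true(all(t_in1[in2]))
  # peripheral residues align to themselves
  per <- !(in1 | in2)
  expect_equal(m$target_res_seq[per], m$template_res_seq[per])
})

test_that("linker residues not in any block become target-only columns", {
  toy <- symmetric_toy(2)
  n_ru <- toy$repeats$ru1$end[1]
  shrunk <- repeat_definition(
    paste0("A:1-", n_ru - 2), # leave two RU1 residues as linker
    paste0("A:", toy$repeats$ru2$start[1], "-", toy$repeats$ru2$end[1]),
    peripheral = paste0("A:", toy$repeats$peripheral$start[1], "-",
                        toy$repeats$peripheral$end[1])
  )
  ru1 <- suppressWarnings(select_residues(toy$structure, shrunk$ru1))
  ru2 <- suppressWarnings(select_residues(toy$structure, shrunk$ru2))
  ra <- align_repeats(ru1, ru2)
  aln <- build_swap_alignment(toy$structure, shrunk, ra$alignment)
  lk <- aln$blocks[aln$blocks$kind == "linker", ]
  expect_equal(nrow(lk), 1)
  tp <- strsplit(aln$template_gapped, "")[[1]]
  expect_true(all(tp[lk$col_start:lk$col_end] == "-"))
})

test_that("swapping the swapped definition recovers the original pairing", {
  toy <- symmetric_toy(3)
  inp <- make_swap_inputs(toy)
  aln1 <- inp$aln
  rep2 <- repeat_definition(
    paste0("A:", toy$repeats$ru2$start[1], "-", toy$repeats$ru2$end[1]),
    paste0("A:", toy$repeats$ru1$start[1], "-", toy$repeats$ru1$end[1]),
    peripheral = paste0("A:", toy$repeats$peripheral$start[1], "-",
                        toy$repeats$peripheral$end[1])
  )
  aln2 <- build_swap_alignment(toy$structure, rep2,
                               swapsmith:::transpose_alignment(inp$ra$alignment))
  # composing the two mappings is the identity on repeat residues
  m1 <- aln1$mapping
  m2 <- aln2$mapping
  key2 <- paste(m2$target_chain, m2$target_res_seq)
  j <- match(paste(m1$template_chain, m1$template_res_seq), key2)
  expect_false(anyNA(j))
  expect_equal(m2$template_res_seq[j], m1$target_res_seq)
  # block order swaps role but keeps RU2-template-first layout
  k1 <- aln1$blocks$kind[aln1$blocks$kind %in% c("ru1_to_ru2", "ru2_to_ru1")]
  k2 <- aln2$blocks$kind[aln2$blocks$kind %in% c("ru1_to_ru2", "ru2_to_ru1")]
  expect_equal(k2, rev(k1))
})

test_that("the assembled template starts with RU2 and conserves atoms", {
  toy <- symmetric_toy(4)
  inp <- make_swap_inputs(toy)
  tmpl <- assemble_swapped_template(toy$structure, toy$repeats, aln = inp$aln)
  expect_equal(tmpl$map$old_res_seq[1], toy$repeats$ru2$start[1])
  n_sel <- nrow(toy$structure) # toy has no linker residues outside blocks
  expect_equal(nrow(tmpl$structure), n_sel)
  expect_equal(tmpl$map$new_res_seq, seq_len(nrow(tmpl$map)))
  # without peripherals: plain RU2+RU1 concatenation
  spec0 <- toy_spec(asymmetry_angle_deg = 0, asymmetry_shift_A = 0,
                    noise_A = 0, peripheral_helices = 0, seed = 4)
  toy0 <- make_toy_transporter(spec0)
  tmpl0 <- assemble_swapped_template(toy0$structure, toy0$repeats)
  expect_equal(tmpl0$order,
               c(toy0$repeats$ru2$start[1]:toy0$repeats$ru2$end[1],
                 toy0$repeats$ru1$start[1]:toy0$repeats$ru1$end[1]))
  expect_equal(nrow(tmpl0$structure), nrow(toy0$structure))
})

test_that("peripheral fragments land on their swapped positions", {
  toy <- symmetric_toy(6)
  inp <- make_swap_inputs(toy)
  tmpl0 <- assemble_swapped_template(toy$structure, toy$repeats, aln = inp$aln)
  model0 <- build_naive_model(tmpl0, inp$aln)
  tmpl <- assemble_swapped_template(toy$structure, toy$repeats,
                                    initial_model = model0, aln = inp$aln)
  # compare reoriented peripheral CA to the ground-truth swapped peripheral
  per_new <- tmpl$map$new_res_seq[tmpl$map$old_res_seq %in%
    (toy$repeats$peripheral$start[1]:toy$repeats$peripheral$end[1])]
  got <- tmpl$structure[tmpl$structure$res_seq %in% per_new &
                          tmpl$structure$name == "CA", ]
  want <- suppressWarnings(select_residues(toy$truth$swapped,
                                           toy$repeats$peripheral))
  want <- want[want$name == "CA", ]
  rmsd <- sqrt(mean((got$x - want$x)^2 + (got$y - want$y)^2 +
                      (got$z - want$z)^2))
  expect_lt(rmsd, 1.0)
})

test_that("symmetric toy template superposes onto the original after C2", {
  toy <- symmetric_toy(7)
  inp <- make_swap_inputs(toy)
  tmpl0 <- assemble_swapped_template(toy$structure, toy$repeats, aln = inp$aln)
  model0 <- build_naive_model(tmpl0, inp$aln)
  tmpl <- assemble_swapped_template(toy$structure, toy$repeats,
                                    initial_model = model0, aln = inp$aln)
  flipped <- apply_transform(tmpl$structure, toy$truth$symmetry)
  # relabel template residues back to original numbering and compare
  orig <- toy$structure
  key <- paste(tmpl$map$old_chain, tmpl$map$old_res_seq)
  ca_t <- flipped[flipped$name == "CA", ]
  ca_o <- orig[orig$name == "CA", ]
  old_seq <- tmpl$map$old_res_seq[match(ca_t$res_seq, tmpl$map$new_res_seq)]
  # the swapped template after C2 occupies the partner repeat's position
  co <- toy$truth$correspondence
  partner <- integer(max(co$res_ru2))
  partner[co$res_ru1] <- co$res_ru2
  partner[co$res_ru2] <- co$res_ru1
  expect_part <- ifelse(old_seq <= length(partner) & partner[old_seq] > 0,
                        partner[old_seq], old_seq)
  j <- match(expect_part, ca_o$res_seq)
  d <- sqrt((ca_t$x - ca_o$x[j])^2 + (ca_t$y - ca_o$y[j])^2 +
              (ca_t$z - ca_o$z[j])^2)
  expect_lt(sqrt(mean(d^2)), 0.1)
})

test_that("gap openings inside helices move to the nearest loop", {
  # 9-residue template: loops at 1-2 and 8-9, helix at 3-7
  tg <- strsplit("ACDEF-GHIK", "")[[1]]
  tp <- strsplit("ACDEFWGHIK", "")[[1]]
  aln <- structure(list(
    target_gapped = paste(tg, collapse = ""),
    template_gapped = paste(tp, collapse = ""),
    blocks = tibble::tibble(kind = "ru1_to_ru2", col_start = 1L, col_end = 10L),
    target_res = tibble::tibble(chain_id = "A", res_seq = 1:9,
                                aa = tg[tg != "-"], class = "ru1"),
    template_res = tibble::tibble(chain_id = "A", res_seq = 101:110,
                                  aa = tp)
  ), class = "swap_alignment")
  aln$mapping <- swapsmith:::rebuild_swap_alignment(aln, tg, tp)$mapping
  ss <- "CCHHHHHHCC" # helix spans the gap column
  ref <- refine_alignment(aln, ss)
  tg2 <- strsplit(ref$target_gapped, "")[[1]]
  expect_equal(which(tg2 == "-"), 9L) # moved right to the first loop column
  expect_equal(attr(ref, "n_moved"), 1L)
  expect_equal(nrow(ref$mapping), nrow(aln$mapping))
  expect_equal(gsub("-", "", ref$target_gapped), gsub("-", "", aln$target_gapped))
})

test_that("gapless alignments pass through refinement unchanged", {
  toy <- symmetric_toy(8)
  aln <- make_swap_inputs(toy)$aln
  ss <- paste(rep("H", nrow(aln$template_res)), collapse = "")
  ref <- refine_alignment(aln, ss)
  expect_equal(ref$target_gapped, aln$target_gapped)
  expect_equal(ref$template_gapped, aln$template_gapped)
  expect_error(refine_alignment(aln, "HHH"), "length")
})

test_that("equidistant gap relocations break ties toward the N terminus", {
  tg <- strsplit("ACDE-GHIK", "")[[1]]
  tp <- strsplit("ACDEFGHIK", "")[[1]]
  aln <- structure(list(
    target_gapped = paste(tg, collapse = ""),
    template_gapped = paste(tp, collapse = ""),
    blocks = tibble::tibble(kind = "ru1_to_ru2", col_start = 1L, col_end = 9L),
    target_res = tibble::tibble(chain_id = "A", res_seq = 1:8,
                                aa = tg[tg != "-"], class = "ru1"),
    template_res = tibble::tibble(chain_id = "A", res_seq = 101:109, aa = tp)
  ), class = "swap_alignment")
  aln$mapping <- swapsmith:::rebuild_swap_alignment(aln, tg, tp)$mapping
  # helix at columns 3-7; the gap at column 5 is 3 columns from both loops
  ss <- "CCHHHHHCC"
  ref <- refine_alignment(aln, ss)
  tg2 <- strsplit(ref$target_gapped, "")[[1]]
  expect_equal(which(tg2 == "-"), 2L)
})

test_that("the CA-geometry fallback flags toy helices as helical", {
  toy <- symmetric_toy(9)
  ss <- assign_ss(toy$structure)
  # helix interiors (away from caps) must be H; straight connectors coil
  per <- toy$repeats$peripheral
  helix_core <- (per$start[1] + 3):(per$end[1] - 3)
  expect_true(all(ss$ss[ss$res_seq %in% helix_core] == "H"))
})

test_that("DSSP output parses into per-residue assignments", {
  hdr <- "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA"
  row <- function(num, res, ch, aa, ss) {
    sprintf("%5d%5d %s %s  %s", num, res, ch, aa, ss)
  }
  p <- tempfile(fileext = ".dssp")
  writeLines(c("==== Secondary Structure Definition ====", hdr,
               row(1, 12, "A", "M", "H"),
               row(2, 13, "A", "G", "G"),
               row(3, 14, "A", "K", "E"),
               row(4, 15, "A", "L", " ")), p)
  d <- read_dssp(p)
  expect_equal(d$res_seq, 12:15)
  expect_equal(d$ss, c("H", "H", "E", "C"))
  expect_equal(d$aa, c("M", "G", "K", "L"))
})
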