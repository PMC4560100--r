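# Gaussian distance restraint generation

test_that("collinear CA positions give the hand-enumerated pair count", {
  s <- ca_structure(cbind(c(0, 10, 20, 30, 70), 0, 0), res_seq = 1:5)
  # residue 6 exists but has no CA: skipped with a warning
  no_ca <- s[1, ]
  no_ca$name <- "N"
  no_ca$res_seq <- 6L
  no_ca$x <- 100
  s <- dplyr::bind_rows(s, no_ca)
  dom <- domain_definition("A:1-5", "A:6-6")
  expect_warning(r <- intra_domain_restraints(s, dom, cutoff = 60), "lack a CA")
  # pairs at exactly 60 A and at 70 A are excluded (strict inequality)
  expect_equal(nrow(r), 8)
  expect_equal(unname(attr(r, "counts")["scaffold"]), 8L)
  expect_equal(attr(r, "n_missing_ca"), 1L)
  expect_true(all(r$sigma_A == 0.1))
})

test_that("a single-residue domain yields no restraints", {
  s <- ca_structure(cbind(c(0, 3, 6), 0, 0), res_seq = 1:3)
  dom <- domain_definition("A:1-1", "A:2-3")
  r <- intra_domain_restraints(s, dom, cutoff = 60)
  expect_equal(unname(attr(r, "counts")["scaffold"]), 0L)
  expect_equal(unname(attr(r, "counts")["transport"]), 1L)
})

test_that("two tight domains give binomial counts and no cross terms", {
  set.seed(41)
  n1 <- 11
  n2 <- 7
  s <- ca_structure(rbind(matrix(rnorm(3 * n1, sd = 3), n1, 3),
                          matrix(rnorm(3 * n2, sd = 3), n2, 3)),
                    res_seq = 1:(n1 + n2))
  dom <- domain_definition(paste0("A:1-", n1), paste0("A:", n1 + 1, "-", n1 + n2))
  r <- intra_domain_restraints(s, dom, cutoff = 60)
  expect_equal(nrow(r), choose(n1, 2) + choose(n2, 2))
  cross <- swapsmith:::in_ranges(r$chain_a, r$res_a, dom$scaffold) !=
    swapsmith:::in_ranges(r$chain_b, r$res_b, dom$scaffold)
  expect_false(any(cross))
})

test_that("counts equal a brute-force enumeration on random fixtures", {
  for (seed in 1:10) {
    s <- random_ca_structure(40, seed = 500 + seed, spread = 20)
    dom <- domain_definition("A:1-25", "A:26-40")
    cutoff <- sample(c(15, 30, 60), 1)
    r <- intra_domain_restraints(s, dom, cutoff = cutoff)
    want <- brute_force_pair_count(s, dom$scaffold, cutoff) +
      brute_force_pair_count(s, dom$transport, cutoff)
    expect_identical(nrow(r), as.integer(want))
  }
})

test_that("restraint targets reproduce measured distances exactly", {
  s <- random_ca_structure(25, seed = 77)
  dom <- domain_definition("A:1-15", "A:16-25")
  r <- intra_domain_restraints(s, dom)
  key <- paste(s$chain_id, s$res_seq)
  d <- sqrt((s$x[match(paste(r$chain_a, r$res_a), key)] -
               s$x[match(paste(r$chain_b, r$res_b), key)])^2 +
            (s$y[match(paste(r$chain_a, r$res_a), key)] -
               s$y[match(paste(r$chain_b, r$res_b), key)])^2 +
            (s$z[match(paste(r$chain_a, r$res_a), key)] -
               s$z[match(paste(r$chain_b, r$res_b), key)])^2)
  expect_equal(r$target_A, d, tolerance = 1e-6)
  # and the structure itself satisfies its own restraints
  expect_equal(as.numeric(restraint_score(s, r)), 0, tolerance = 1e-9)
})

test_that("restraint sets are monotone in the cutoff", {
  s <- random_ca_structure(30, seed = 91, spread = 12)
  dom <- domain_definition("A:1-18", "A:19-30")
  keys <- function(r) paste(r$res_a, r$res_b)
  r1 <- intra_domain_restraints(s, dom, cutoff = 10)
  r2 <- intra_domain_restraints(s, dom, cutoff = 25)
  r3 <- intra_domain_restraints(s, dom, cutoff = 60)
  expect_true(all(keys(r1) %in% keys(r2)))
  expect_true(all(keys(r2) %in% keys(r3)))
})

ligand_complex <- function() {
  prot <- ca_structure(cbind(c(0, 3.8, 7.6, 11.4), 0, 0), res_seq = 1:4)
  lig <- tibble::tibble(
    serial = 5L, name = "C1", altloc = " ", res_name = "LIG",
    chain_id = "A", res_seq = 100L, i_code = " ",
    x = 3.8, y = 3.4, z = 0, occupancy = 1, element = "C", is_hetatm = TRUE
  )
  hyd <- tibble::tibble(
    serial = 6L, name = "H1", altloc = " ", res_name = "LIG",
    chain_id = "A", res_seq = 100L, i_code = " ",
    x = 3.8, y = 3.0, z = 0, occupancy = 1, element = "H", is_hetatm = TRUE
  )
  dplyr::bind_rows(prot, lig, hyd)
}

test_that("a ligand atom just inside the cutoff yields one restraint", {
  s <- ligand_complex()
  r <- ligand_restraints(s, "LIG", cutoff = 3.5)
  expect_equal(nrow(r), 1)
  expect_equal(r$res_b, 2L)
  expect_equal(r$target_A, 3.4, tolerance = 1e-9)
  expect_false(any(grepl("^H", r$atom_a))) # hydrogens never restrained
  expect_error(ligand_restraints(s, "ABSENT"), "empty")
})

test_that("the 3.5 A set is a subset of the 5 A set", {
  set.seed(55)
  prot <- random_ca_structure(20, seed = 56, spread = 6)
  lig <- prot[1:3, ]
  lig$res_seq <- 201:203
  lig$res_name <- "LIG"
  lig$is_hetatm <- TRUE
  lig$x <- lig$x + runif(3, 1, 4)
  s <- dplyr::bind_rows(prot, lig)
  r35 <- ligand_restraints(s, "LIG", cutoff = 3.5)
  r50 <- ligand_restraints(s, "LIG", cutoff = 5)
  k <- function(r) paste(r$res_a, r$atom_a, r$res_b, r$atom_b)
  expect_true(all(k(r35) %in% k(r50)))
  expect_gte(nrow(r50), nrow(r35))
})

test_that("named sodium-site mode returns the specified partners", {
  # miniature VcCNT-like site: backbone O of N149/V152/I184, S183 OG,
  # one water, one sodium ion
  mk <- function(res_seq, res_name, name, x, element = substr(name, 1, 1)) {
    tibble::tibble(serial = 0L, name = name, altloc = " ", res_name = res_name,
                   chain_id = "A", res_seq = as.integer(res_seq), i_code = " ",
                   x = x, y = 0, z = 0, occupancy = 1, element = element,
                   is_hetatm = res_name %in% c("HOH", "NA"))
  }
  s <- dplyr::bind_rows(
    mk(149, "ASN", "CA", 0), mk(149, "ASN", "O", 2),
    mk(152, "VAL", "CA", 4), mk(152, "VAL", "O", 6),
    mk(183, "SER", "CA", 8), mk(183, "SER", "OG", 10),
    mk(184, "ILE", "CA", 12), mk(184, "ILE", "O", 14),
    mk(601, "HOH", "O", 16), mk(602, "HOH", "O", 40),
    mk(701, "NA", "NA", 15)
  )
  r <- ligand_restraints(s, "NA", cutoff = 0, named_pairs = vccnt_na_pairs())
  got <- paste(r$res_b, r$atom_b)
  expect_setequal(got, c("149 O", "152 O", "183 OG", "184 O", "601 O"))
  # the nearest water was chosen and distances measured, not cutoff-limited
  expect_true(all(r$target_A > 0))
  expect_equal(nrow(r), 5)
})

test_that("restraints map onto model numbering through the alignment", {
  toy <- symmetric_toy(10)
  ru1 <- suppressWarnings(select_residues(toy$structure, toy$repeats$ru1))
  ru2 <- suppressWarnings(select_residues(toy$structure, toy$repeats$ru2))
  ra <- align_repeats(ru1, ru2)
  aln <- build_swap_alignment(toy$structure, toy$repeats, ra$alignment)
  r <- intra_domain_restraints(toy$structure, toy$domains, cutoff = 15)
  mapped <- map_restraints(r, aln)
  expect_equal(nrow(mapped), nrow(r)) # complete pairing: nothing dropped
  # template RU2 residues map onto target RU1 residues
  m <- aln$mapping
  look <- stats::setNames(m$target_res_seq, m$template_res_seq)
  expect_equal(mapped$res_a, unname(look[as.character(r$res_a)]))
})
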