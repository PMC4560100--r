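# shared fixtures, all generated in code

# minimal atom tibble from residue-level CA coordinates
ca_structure <- function(coords, res_seq = seq_len(nrow(coords)),
                         chain_id = "A", res_name = "ALA",
                         is_hetatm = FALSE) {
  tibble::tibble(
    serial = seq_len(nrow(coords)),
    name = "CA", altloc = " ",
    res_name = rep_len(res_name, nrow(coords)),
    chain_id = rep_len(chain_id, nrow(coords)),
    res_seq = as.integer(res_seq), i_code = " ",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occupancy = 1,
    element = "C",
    is_hetatm = rep_len(is_hetatm, nrow(coords))
  )
}

# random globular CA cloud with reproducible coordinates
random_ca_structure <- function(n, seed, spread = 15) {
  set.seed(seed)
  ca_structure(matrix(stats::rnorm(3 * n, sd = spread), n, 3))
}

# hand-rolled PDB text lines for parser tests
pdb_line <- function(serial, name, res_name, chain, res_seq, x, y, z,
                     occ = 1, altloc = " ", i_code = " ", het = FALSE,
                     element = substr(name, 1, 1)) {
  name4 <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, name4, altloc, res_name,
          chain, res_seq, i_code, x, y, z, occ, 0, element)
}

write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# noiseless, perfectly symmetric toy (identical repeats)
symmetric_toy <- function(seed = 1) {
  make_toy_transporter(toy_spec(asymmetry_angle_deg = 0, asymmetry_shift_A = 0,
                                noise_A = 0, seed = seed))
}

# default study-condition toy (20 deg / 5 A asymmetry, 0.3 A jitter)
default_toy <- function(seed = 1) {
  make_toy_transporter(toy_spec(seed = seed))
}

# brute-force O(n^2) restraint-count oracle: double loop over CA pairs
brute_force_pair_count <- function(s, ranges, cutoff) {
  sel <- suppressWarnings(select_residues(s, ranges))
  ca <- sel[sel$name == "CA" & !sel$is_hetatm, , drop = FALSE]
  n <- nrow(ca)
  count <- 0L
  if (n < 2) return(0L)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((ca$x[i] - ca$x[j])^2 + (ca$y[i] - ca$y[j])^2 +
                  (ca$z[i] - ca$z[j])^2)
      if (d < cutoff) count <- count + 1L
    }
  }
  count
}

expect_equal_coords <- function(a, b, tol = 1e-3) {
  expect_equal(cbind(a$x, a$y, a$z), cbind(b$x, b$y, b$z), tolerance = tol)
}
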