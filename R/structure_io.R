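#' Read a PDB-format structure into an atom tibble
#'
#' Parses fixed-column ATOM/HETATM records into one row per atom. The result
#' is the package's structure container: a tibble with columns `serial`,
#' `name`, `altloc`, `res_name`, `chain_id`, `res_seq`, `i_code`, `x`, `y`,
#' `z`, `occupancy`, `element`, `is_hetatm`, in file order. Residues are
#' addressed by author numbering `(chain_id, res_seq, i_code)` throughout.
#'
#' Alternate locations are resolved to a single conformer per atom: the
#' highest occupancy wins, ties broken by the alphabetically first altloc
#' identifier. HETATM groups (ligands, ions, waters) are retained and
#' flagged via `is_hetatm`.
#'
#' @param path Path to a PDB file.
#' @param model Model number to read from multi-model files (1-based block
#'   index; default first model).
#' @param chain Optional chain identifier; if given, only that chain is
#'   returned.
#' @return A tibble of atom records with attributes `title` and
#'   `provenance`.
#' @examples
#' toy <- make_toy_transporter(toy_spec(seed = 1))
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(toy$structure, f)
#' s <- read_pdb(f)
#' nrow(s)
#' @export
read_pdb <- function(path, model = 1L, chain = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)

  # model selection: lines between the model-th MODEL record and its ENDMDL
  model_starts <- which(trimws(rec) == "MODEL")
  keep <- rep(TRUE, length(lines))
  if (length(model_starts) > 0) {
    if (model > length(model_starts)) {
      abort(paste0("model ", model, " requested but file has ",
                   length(model_starts), " models"))
    }
    ends <- which(trimws(rec) == "ENDMDL")
    m0 <- model_starts[model]
    m1 <- ends[ends > m0][1]
    if (is.na(m1)) m1 <- length(lines)
    keep <- seq_along(lines) >= m0 & seq_along(lines) <= m1
  }

  is_atom <- keep & rec %in% c("ATOM  ", "HETATM")
  idx <- which(is_atom)
  if (sum(rec %in% "ATOM  ") == 0) {
    abort(paste0("no ATOM records in ", path))
  }
  al <- lines[idx]
  bad <- nchar(al) < 54
  if (any(bad)) {
    abort(paste0("malformed fixed-column ATOM/HETATM record at line ",
                 idx[which(bad)[1]], " of ", path))
  }
  fx <- function(a, b) substr(al, a, b)
  num <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    if (anyNA(out)) {
      abort(paste0("malformed ", what, " field at line ",
                   idx[which(is.na(out))[1]], " of ", path))
    }
    out
  }
  occ <- trimws(fx(55, 60))
  s <- tibble(
    serial = as.integer(num(fx(7, 11), "serial")),
    name = trimws(fx(13, 16)),
    altloc = fx(17, 17),
    res_name = trimws(fx(18, 20)),
    chain_id = fx(22, 22),
    res_seq = as.integer(num(fx(23, 26), "residue number")),
    i_code = fx(27, 27),
    x = num(fx(31, 38), "x coordinate"),
    y = num(fx(39, 46), "y coordinate"),
    z = num(fx(47, 54), "z coordinate"),
    occupancy = ifelse(nzchar(occ), suppressWarnings(as.numeric(occ)), 1),
    element = trimws(fx(77, 78)),
    is_hetatm = rec[idx] == "HETATM"
  )
  s$occupancy[is.na(s$occupancy)] <- 1
  if (!all(is.finite(s$x) & is.finite(s$y) & is.finite(s$z))) {
    abort("non-finite coordinates in input")
  }
  s$element[!nzchar(s$element)] <- guess_element(s$name[!nzchar(s$element)])

  if (!is.null(chain)) s <- s[s$chain_id %in% chain, , drop = FALSE]

  # altloc resolution: per residue and atom name keep highest occupancy,
  # ties broken by the alphabetically first altloc (blank sorts first)
  if (any(nzchar(trimws(s$altloc)))) {
    pos <- seq_len(nrow(s))
    key <- paste(s$chain_id, s$res_seq, s$i_code, s$name, sep = "\r")
    ord <- order(key, -s$occupancy, s$altloc, pos)
    keep_row <- ord[!duplicated(key[ord])]
    s <- s[sort(keep_row), , drop = FALSE]
  }

  title <- paste(trimws(substr(lines[rec == "TITLE "], 11, 80)), collapse = " ")
  attr(s, "title") <- title
  attr(s, "provenance") <- paste0(
    "read_pdb(", path, ", model=", model,
    if (!is.null(chain)) paste0(", chain=", paste(chain, collapse = "+")) else "",
    "); altloc: highest occupancy, alphabetical tiebreak")
  s
}

guess_element <- function(name) {
  e <- toupper(substr(gsub("^[0-9 ]+", "", name), 1, 1))
  e[e == ""] <- "X"
  e
}

#' Residue-level view of a structure
#'
#' @param s An atom tibble (see [read_pdb()]).
#' @return A tibble with one row per residue, in file order, with columns
#'   `chain_id`, `res_seq`, `i_code`, `res_name`, `aa` (one-letter code,
#'   `X` for non-standard groups) and `is_hetatm`.
#' @export
residue_table <- function(s) {
  key <- paste(s$chain_id, s$res_seq, s$i_code, sep = "\r")
  first <- !duplicated(key)
  tibble(
    chain_id = s$chain_id[first],
    res_seq = s$res_seq[first],
    i_code = s$i_code[first],
    res_name = s$res_name[first],
    aa = aa_one(s$res_name[first]),
    is_hetatm = s$is_hetatm[first]
  )
}

#' Select residues by author-numbered ranges
#'
#' Returns the atoms of all residues whose `(chain_id, res_seq)` fall inside
#' any of the given ranges, preserving file order. Residue positions covered
#' by a range but absent from the structure are skipped and counted; the
#' count is attached as attribute `n_missing` and reported as a warning when
#' non-zero.
#'
#' @param s An atom tibble.
#' @param ranges A residue range specification (see [residue_ranges()]).
#' @return The selected atom tibble.
#' @examples
#' toy <- make_toy_transporter(toy_spec(seed = 1))
#' sel <- select_residues(toy$structure, toy$domains$scaffold)
#' @export
select_residues <- function(s, ranges) {
  ranges <- if (inherits(ranges, "tbl_df") || is.data.frame(ranges)) {
    validate_ranges(as_tibble(ranges))
  } else {
    residue_ranges(ranges)
  }
  hit <- in_ranges(s$chain_id, s$res_seq, ranges)
  out <- s[hit, , drop = FALSE]
  present <- unique(paste(out$chain_id, out$res_seq, sep = "\r"))
  n_missing <- range_span(ranges) - length(present)
  if (n_missing > 0) {
    warn(paste0(n_missing, " residue position(s) in the requested ranges ",
                "are absent from the structure"))
  }
  attr(out, "n_missing") <- n_missing
  attr(out, "title") <- attr(s, "title")
  attr(out, "provenance") <- attr(s, "provenance")
  out
}

#' Write a structure as fixed-column PDB
#'
#' Writes ATOM/HETATM records (plus TER/END). With `renumber_from`, residues
#' are renumbered consecutively from that value in file order, insertion
#' codes are cleared, and the original numbering is recorded in a
#' `REMARK 300` block so provenance survives the round trip. Coordinates
#' survive a read/write round trip to 3 decimals (the format's precision).
#'
#' @param s An atom tibble.
#' @param path Output path.
#' @param renumber_from Optional integer; first residue number of the
#'   renumbered output.
#' @return Invisibly, the numbering map tibble (`old_chain`, `old_res_seq`,
#'   `old_i_code`, `new_res_seq`), or `NULL` when not renumbering.
#' @export
write_pdb <- function(s, path, renumber_from = NULL) {
  if (nrow(s) == 0) abort("refusing to write an empty structure")
  if (nrow(s) > 99999L) {
    abort("structure has more than 99999 atoms; fixed-column PDB cannot represent it")
  }
  key <- paste(s$chain_id, s$res_seq, s$i_code, sep = "\r")
  res_idx <- match(key, unique(key))
  map <- NULL
  res_seq <- s$res_seq
  i_code <- s$i_code
  if (!is.null(renumber_from)) {
    new_seq <- renumber_from + res_idx - 1L
    first <- !duplicated(key)
    map <- tibble(
      old_chain = s$chain_id[first], old_res_seq = s$res_seq[first],
      old_i_code = s$i_code[first], new_res_seq = new_seq[first]
    )
    res_seq <- new_seq
    i_code <- " "
  }
  name4 <- ifelse(nchar(s$name) >= 4, substr(s$name, 1, 4),
                  sprintf("%-3s", s$name))
  name4 <- ifelse(nchar(name4) == 4, name4, paste0(" ", name4))
  lines <- sprintf(
    "%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(s$is_hetatm, "HETATM", "ATOM"),
    (seq_len(nrow(s)) - 1L) %% 99999L + 1L,
    name4, substr(paste0(s$altloc, " "), 1, 1), s$res_name, s$chain_id,
    res_seq, i_code, s$x, s$y, s$z, s$occupancy, 0, s$element
  )
  header <- character()
  title <- attr(s, "title")
  if (!is.null(title) && nzchar(title)) {
    header <- c(header, sprintf("TITLE     %-60s", substr(title, 1, 60)))
  }
  if (!is.null(map)) {
    header <- c(header,
      "REMARK 300 RESIDUES RENUMBERED; ORIGINAL NUMBERING FOLLOWS",
      sprintf("REMARK 300 RENUM %1s %4d%1s -> %4d",
              map$old_chain, map$old_res_seq, map$old_i_code, map$new_res_seq))
  }
  # TER after the last non-het atom of each chain
  ter <- character(0)
  out <- character(0)
  chains <- unique(s$chain_id)
  body <- split(seq_len(nrow(s)), factor(s$chain_id, levels = chains))
  for (ch in chains) {
    ii <- body[[ch]]
    out <- c(out, lines[ii], "TER")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, out, "END"), con)
  invisible(map)
}

# n x 3 coordinate matrix of the CA atoms of s, in residue (file) order
ca_coords <- function(s) {
  ca <- s[s$name == "CA" & !s$is_hetatm, , drop = FALSE]
  m <- cbind(ca$x, ca$y, ca$z)
  rownames(m) <- paste(ca$chain_id, ca$res_seq, sep = ":")
  attr(m, "chain_id") <- ca$chain_id
  attr(m, "res_seq") <- ca$res_seq
  m
}
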