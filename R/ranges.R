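#' Residue range sets
#'
#' A residue range set is a tibble with columns `chain_id`, `start`, `end`
#' describing author-numbered, 1-based inclusive residue intervals, the
#' addressing convention used throughout the package (e.g. "residues 12-77
#' plus 129-218" for the Glt_Ph scaffold domain). Ranges within one set must
#' not overlap.
#'
#' @param x A specification: a string such as `"A:12-77,A:129-218"`
#'   (chain prefix optional, `"12-77,129-218"` uses `chain`), a data frame
#'   with columns `chain_id`/`start`/`end`, or a numeric vector
#'   `c(start, end)`.
#' @param chain Default chain identifier for entries without an explicit
#'   chain prefix.
#' @return A tibble of class with columns `chain_id`, `start`, `end`.
#' @examples
#' residue_ranges("A:12-77,A:129-218")
#' residue_ranges("150-334", chain = "A")
#' @export
residue_ranges <- function(x, chain = "A") {
  if (is.data.frame(x)) {
    stopifnot(all(c("start", "end") %in% names(x)))
    out <- tibble(
      chain_id = as.character(x$chain_id %||% chain),
      start = as.integer(x$start),
      end = as.integer(x$end)
    )
    if (!"chain_id" %in% names(x)) out$chain_id <- chain
  } else if (is.numeric(x)) {
    if (length(x) != 2) abort("numeric range must be c(start, end)")
    out <- tibble(chain_id = chain, start = as.integer(x[1]), end = as.integer(x[2]))
  } else if (is.character(x)) {
    parts <- trimws(unlist(strsplit(paste(x, collapse = ","), ",")))
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0) abort("empty range specification")
    parsed <- lapply(parts, function(p) {
      m <- regmatches(p, regexec("^(?:([A-Za-z0-9]):)?(-?[0-9]+)-(-?[0-9]+)$", p))[[1]]
      if (length(m) == 0) abort(paste0("cannot parse residue range '", p, "'"))
      tibble(
        chain_id = if (nzchar(m[2])) m[2] else chain,
        start = as.integer(m[3]), end = as.integer(m[4])
      )
    })
    out <- bind_rows(parsed)
  } else {
    abort("unsupported range specification")
  }
  validate_ranges(out)
}

validate_ranges <- function(r) {
  if (any(r$start > r$end)) abort("range start must be <= end")
  for (ch in unique(r$chain_id)) {
    rr <- r[r$chain_id == ch, , drop = FALSE]
    rr <- rr[order(rr$start), , drop = FALSE]
    if (nrow(rr) > 1 && any(rr$start[-1] <= rr$end[-nrow(rr)])) {
      abort(paste0("overlapping ranges on chain ", ch))
    }
  }
  r
}

#' @rdname residue_ranges
#' @param ranges A residue range set.
#' @return `range_span()`: total number of residue positions covered.
#' @export
range_span <- function(ranges) {
  sum(ranges$end - ranges$start + 1L)
}

# logical membership of (chain_id, res_seq) vectors in a range set
in_ranges <- function(chain_id, res_seq, ranges) {
  hit <- rep(FALSE, length(res_seq))
  for (k in seq_len(nrow(ranges))) {
    hit <- hit | (chain_id == ranges$chain_id[k] &
                    res_seq >= ranges$start[k] & res_seq <= ranges$end[k])
  }
  hit
}

# set ops used by definitions below
ranges_disjoint <- function(a, b) {
  for (i in seq_len(nrow(a))) {
    ov <- b$chain_id == a$chain_id[i] & b$start <= a$end[i] & b$end >= a$start[i]
    if (any(ov)) return(FALSE)
  }
  TRUE
}

#' Repeat unit definition
#'
#' Bundles the residue ranges of the two inverted-topology repeat units and
#' of any peripheral segments (segments outside both repeats, e.g. helices
#' TM4a/4b in Glt_Ph). Repeat boundaries are user input: automatic repeat
#' detection is deliberately out of scope, since no reliable automated
#' strategy exists for asymmetric, low-identity repeats.
#'
#' @param ru1,ru2 Residue range specifications (see [residue_ranges()]) for
#'   repeat units 1 and 2.
#' @param peripheral Optional ranges outside both repeats.
#' @param chain Default chain for unprefixed range strings.
#' @return A list of class `repeat_definition` with tibble elements
#'   `ru1`, `ru2`, `peripheral`.
#' @examples
#' repeat_definition("12-108,335-416", "150-334", peripheral = "109-149")
#' @export
repeat_definition <- function(ru1, ru2, peripheral = NULL, chain = "A") {
  ru1 <- residue_ranges(ru1, chain)
  ru2 <- residue_ranges(ru2, chain)
  if (!ranges_disjoint(ru1, ru2)) abort("repeat units must be disjoint")
  if (!is.null(peripheral)) {
    peripheral <- residue_ranges(peripheral, chain)
    if (!ranges_disjoint(peripheral, ru1) || !ranges_disjoint(peripheral, ru2)) {
      abort("peripheral ranges must be disjoint from both repeats")
    }
  } else {
    peripheral <- tibble(chain_id = character(), start = integer(), end = integer())
  }
  structure(list(ru1 = ru1, ru2 = ru2, peripheral = peripheral),
            class = "repeat_definition")
}

#' Scaffold/transport domain definition
#'
#' Bundles the residue ranges of the static scaffold/oligomerization domain
#' and of the mobile transport domain of an elevator-type transporter.
#'
#' @param scaffold,transport Residue range specifications
#'   (see [residue_ranges()]).
#' @param chain Default chain for unprefixed range strings.
#' @return A list of class `domain_definition` with tibble elements
#'   `scaffold` and `transport`.
#' @examples
#' domain_definition("12-77,129-218", "78-128,219-416")
#' @export
domain_definition <- function(scaffold, transport, chain = "A") {
  scaffold <- residue_ranges(scaffold, chain)
  transport <- residue_ranges(transport, chain)
  if (!ranges_disjoint(scaffold, transport)) {
    abort("scaffold and transport domains must be disjoint")
  }
  structure(list(scaffold = scaffold, transport = transport),
            class = "domain_definition")
}

#' Packaged repeat and domain presets
#'
#' Residue-range presets for the two calibration transporters: the aspartate
#' transporter Glt_Ph (repeats 12-108 + 335-416 and 150-334; scaffold
#' 12-77 + 129-218, transport 78-128 + 219-416) and the concentrative
#' nucleoside transporter VcCNT (repeats 119-229 and 294-416; scaffold
#' 2-137 + 241-311, transport 138-229 + 312-416).
#'
#' @param chain Chain identifier the ranges apply to (protomer chain).
#' @return A [repeat_definition()] or [domain_definition()].
#' @export
glt_ph_repeats <- function(chain = "A") {
  repeat_definition("12-108,335-416", "150-334", peripheral = "109-149",
                    chain = chain)
}

#' @rdname glt_ph_repeats
#' @export
glt_ph_domains <- function(chain = "A") {
  domain_definition("12-77,129-218", "78-128,219-416", chain = chain)
}

#' @rdname glt_ph_repeats
#' @export
vccnt_repeats <- function(chain = "A") {
  repeat_definition("119-229", "294-416", peripheral = "2-118,230-293",
                    chain = chain)
}

#' @rdname glt_ph_repeats
#' @export
vccnt_domains <- function(chain = "A") {
  domain_definition("2-137,241-311", "138-229,312-416", chain = chain)
}

#' Preset ligand-site restraint generators
#'
#' Convenience wrappers around [ligand_restraints()] carrying the
#' calibrated site parameters: for Glt_Ph, all heavy-atom contacts of the
#' aspartate substrate and the two Na+ ions within 5 Angstrom; for VcCNT,
#' heavy-atom contacts of the uridine substrate within 3.5 Angstrom plus
#' the named sodium-site partners of [vccnt_na_pairs()].
#'
#' @param s Atom tibble containing the ligand HETATM groups.
#' @param ligands HETATM residue names of the substrate/ion groups.
#' @param cutoff Distance cutoff in Angstrom (strict `<`).
#' @param sigma Gaussian standard deviation in Angstrom.
#' @param chain Chain carrying the named sodium-site partners (VcCNT).
#' @return A restraint tibble (see [ligand_restraints()]).
#' @export
glt_ph_site_restraints <- function(s, ligands = c("ASP", "NA"), cutoff = 5,
                                   sigma = 0.1) {
  ligand_restraints(s, ligands, cutoff = cutoff, sigma = sigma)
}

#' @rdname glt_ph_site_restraints
#' @export
vccnt_site_restraints <- function(s, ligands = c("URI", "NA"), cutoff = 3.5,
                                  sigma = 0.1, chain = "A") {
  na_part <- ligand_restraints(s, "NA", cutoff = 0, sigma = sigma,
                               named_pairs = vccnt_na_pairs(chain))
  uri <- ligand_restraints(s, setdiff(ligands, "NA"), cutoff = cutoff,
                           sigma = sigma)
  dedupe_restraints(bind_rows(uri, na_part))
}

#' @rdname glt_ph_repeats
#' @details `vccnt_na_pairs()` returns the named sodium-site restraint
#'   partners for VcCNT: the backbone O atoms of N149, V152 and I184, the
#'   S183 hydroxyl oxygen, and a crystallographic water oxygen (resolved to
#'   the water O nearest the ion at restraint-generation time).
#' @export
vccnt_na_pairs <- function(chain = "A") {
  tibble(
    chain_b = chain,
    res_b = c(149L, 152L, 184L, 183L, NA),
    atom_b = c("O", "O", "O", "OG", "O"),
    res_name_b = c("ASN", "VAL", "ILE", "SER", "HOH")
  )
}
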