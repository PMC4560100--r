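#' Quantify the conformational change between two conformations
#'
#' The elevator-motion analysis: (1) superpose the model onto the reference
#' using scaffold-domain CA atoms (or `fit_ranges`); (2) Kabsch-fit the
#' transport-domain CA atoms of the scaffold-fitted model onto the
#' reference transport domain, giving the rigid transform that carries the
#' reference transport domain to its position in the model; (3) decompose
#' that transform into rotation axis/angle and the transport-centroid
#' displacement in the membrane frame; (4) report per-domain RMSD and
#' TM-score, each from its own domain superposition (the internal
#' difference of the domain between the two conformations); (5) compute the
#' per-residue CA displacement profile after the scaffold fit.
#'
#' Residues are paired across structures by `(chain, res_seq)` identity.
#'
#' @param model,reference Atom tibbles sharing residue numbering over the
#'   domains (the reference is assumed membrane-oriented).
#' @param domains A [domain_definition()].
#' @param frame A [membrane_frame()].
#' @param fit_ranges Optional override of the superposition selection
#'   (defaults to the full scaffold definition; pass the oligomerization
#'   helices only for the narrower convention).
#' @return An object of class `conf_change`; see [tidy.conf_change()],
#'   [glance.conf_change()], [autoplot.conf_change()].
#' @examples
#' toy <- make_toy_transporter(toy_spec(seed = 1))
#' cc <- analyze_change(toy$truth$swapped, toy$structure, toy$domains)
#' glance(cc)
#' @export
analyze_change <- function(model, reference, domains,
                           frame = membrane_frame(), fit_ranges = NULL) {
  stopifnot(inherits(domains, "domain_definition"))
  fit_ranges <- fit_ranges %||% domains$scaffold
  cm <- ca_coords(model)
  cr <- ca_coords(reference)
  shared <- intersect(rownames(cr), rownames(cm))
  im <- match(shared, rownames(cm))
  ir <- match(shared, rownames(cr))
  ch <- attr(cr, "chain_id")[ir]
  rs <- attr(cr, "res_seq")[ir]
  in_scaf <- in_ranges(ch, rs, domains$scaffold)
  in_trans <- in_ranges(ch, rs, domains$transport)
  if (sum(in_scaf) < 3 || sum(in_trans) < 3) {
    abort("fewer than 3 shared CA atoms in a domain")
  }
  fit_ranges_tbl <- if (is.data.frame(fit_ranges)) as_tibble(fit_ranges) else residue_ranges(fit_ranges)
  in_fit <- in_ranges(ch, rs, fit_ranges_tbl)
  if (sum(in_fit) < 3) abort("fewer than 3 shared CA atoms in fit_ranges")

  M <- cm[im, , drop = FALSE]
  Rf <- cr[ir, , drop = FALSE]

  scaffold_fit <- superpose(M[in_fit, , drop = FALSE], Rf[in_fit, , drop = FALSE])
  Mf <- apply_transform(M, scaffold_fit$transform)

  # motion of the transport domain: reference -> (scaffold-fitted) model
  trans_fit <- superpose(Rf[in_trans, , drop = FALSE], Mf[in_trans, , drop = FALSE])
  centroid <- colMeans(Rf[in_trans, , drop = FALSE])
  motion <- decompose_transform(trans_fit$transform, frame, centroid)

  dom_metrics <- lapply(list(scaffold = in_scaf, transport = in_trans),
                        function(sel) {
    own <- superpose(M[sel, , drop = FALSE], Rf[sel, , drop = FALSE])
    tm <- tm_score(M[sel, , drop = FALSE], Rf[sel, , drop = FALSE],
                   l_norm = sum(sel))
    tibble(n_res = sum(sel), rmsd_A = own$rmsd, tm_score = as.numeric(tm))
  })
  dom_tbl <- bind_rows(dom_metrics, .id = "domain")

  d <- sqrt(rowSums((Mf - Rf)^2))
  profile <- tibble(
    chain_id = ch, res_seq = rs,
    domain = ifelse(in_scaf, "scaffold", ifelse(in_trans, "transport", "other")),
    displacement_A = d
  )
  profile <- profile[order(ir), , drop = FALSE]

  structure(list(
    motion = motion,
    domains = dom_tbl,
    profile = profile,
    transport_transform = trans_fit$transform,
    transport_fit_rmsd = trans_fit$rmsd,
    scaffold_fit = scaffold_fit,
    meta = list(
      frame = frame,
      fit = "scaffold CA superposition; transport motion reference -> model",
      displacement_convention = "transport-domain centroid displacement in the membrane frame",
      n_shared = length(shared)
    )
  ), class = "conf_change")
}

#' @export
print.conf_change <- function(x, ...) {
  cat("Conformational-change report\n")
  cat(sprintf("  transport rotation : %.1f deg about (%.2f, %.2f, %.2f)\n",
              x$motion$angle_deg, x$motion$axis[1], x$motion$axis[2],
              x$motion$axis[3]))
  cat(sprintf("  displacement (x,y,z): (%.1f, %.1f, %.1f) A in the membrane frame\n",
              x$motion$displacement[1], x$motion$displacement[2],
              x$motion$displacement[3]))
  cat(sprintf("  axis vs membrane normal: %.1f deg\n",
              x$motion$axis_membrane_angle_deg))
  for (k in seq_len(nrow(x$domains))) {
    cat(sprintf("  %-9s n=%3d  rmsd %.2f A  TM-score %.3f\n",
                x$domains$domain[k], x$domains$n_res[k],
                x$domains$rmsd_A[k], x$domains$tm_score[k]))
  }
  invisible(x)
}

#' Tidy methods for conformational-change reports
#'
#' `tidy()` returns one row per domain (RMSD, TM-score, mean and maximum
#' displacement); `glance()` returns a one-row summary with the motion
#' decomposition and headline similarity metrics.
#'
#' @param x A `conf_change` object.
#' @param ... Unused.
#' @method tidy conf_change
#' @export
tidy.conf_change <- function(x, ...) {
  prof <- x$profile
  agg <- prof |>
    dplyr::filter(.data$domain != "other") |>
    group_by(.data$domain) |>
    summarise(mean_displacement_A = mean(.data$displacement_A),
              max_displacement_A = max(.data$displacement_A),
              .groups = "drop")
  left_join(x$domains, agg, by = "domain")
}

#' @rdname tidy.conf_change
#' @method glance conf_change
#' @export
glance.conf_change <- function(x, ...) {
  bind_cols(
    as_tibble(x$motion),
    tibble(
      scaffold_rmsd_A = x$domains$rmsd_A[x$domains$domain == "scaffold"],
      transport_rmsd_A = x$domains$rmsd_A[x$domains$domain == "transport"],
      scaffold_tm = x$domains$tm_score[x$domains$domain == "scaffold"],
      transport_tm = x$domains$tm_score[x$domains$domain == "transport"],
      n_shared = x$meta$n_shared
    )
  )
}

#' @rdname tidy.conf_change
#' @param object A `conf_change` object.
#' @method autoplot conf_change
#' @export
autoplot.conf_change <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$res_seq, y = .data$displacement_A,
                               colour = .data$domain)) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey70") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Residue (author numbering)",
                  y = expression("C" * alpha * " displacement (" * ring(A) * ")"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write a conformational-change report to disk
#'
#' Emits the report as JSON (motion, per-domain metrics, metadata) plus the
#' displacement profile as TSV.
#'
#' @param x A `conf_change` object.
#' @param json_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_conf_change <- function(x, json_path = NULL, tsv_path = NULL) {
  written <- character(0)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      motion = as.list(as_tibble(x$motion)),
      domains = x$domains,
      transport_fit_rmsd = x$transport_fit_rmsd,
      meta = list(fit = x$meta$fit,
                  displacement_convention = x$meta$displacement_convention,
                  n_shared = x$meta$n_shared)
    ), json_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, json_path)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(x$profile, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, tsv_path)
  }
  invisible(written)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
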