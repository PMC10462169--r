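# Post-generation screening cascade: multi-target affinity thresholds,
# Lipinski's rule of five, property-range classification over a ten-column
# ADMET/physicochemical/medicinal-chemistry profile, novelty filtering
# against the references, and percent-excellent ranking.

.property_names <- c("caco2", "f20", "pgp_sub", "pgp_inh", "vd",
                     "t_half", "fdamdd", "sas", "logp", "logs")

#' Default property range table
#'
#' The optimal ("excellent") and acceptable ("medium") ranges of the ten
#' screened properties: Caco-2 permeability (> -5.15), the five
#' probability-like ADMET scores F20%, Pgp-substrate, Pgp-inhibitor, T1/2
#' and FDAMDD (excellent 0-0.3, medium 0.3-0.7), volume of distribution
#' (0.04-20 L/kg), synthetic accessibility score (< 6), log P (0-3) and
#' log S (-4-0.5). Excellent intervals are closed at finite printed
#' endpoints; where excellent and medium ranges meet (0.3) the boundary
#' belongs to the excellent class; one-sided ranges are strict. Properties
#' without a medium range fail outright outside the excellent one.
#'
#' @return data.frame with one row per property: interval endpoints,
#'   open/closed flags and whether a medium range exists.
#' @export
default_range_table <- function() {
  row <- function(property, elo, ehi, elo_open, ehi_open,
                  mlo = NA_real_, mhi = NA_real_,
                  mlo_open = NA, mhi_open = NA) {
    data.frame(property = property, excellent_lo = elo, excellent_hi = ehi,
               excellent_lo_open = elo_open, excellent_hi_open = ehi_open,
               medium_lo = mlo, medium_hi = mhi,
               medium_lo_open = mlo_open, medium_hi_open = mhi_open,
               has_medium = !is.na(mlo), stringsAsFactors = FALSE)
  }
  score <- function(p) row(p, 0, 0.3, FALSE, FALSE, 0.3, 0.7, TRUE, FALSE)
  rbind(
    row("caco2", -5.15, Inf, TRUE, TRUE),
    score("f20"), score("pgp_sub"), score("pgp_inh"),
    row("vd", 0.04, 20, FALSE, FALSE),
    score("t_half"), score("fdamdd"),
    row("sas", -Inf, 6, TRUE, TRUE),
    row("logp", 0, 3, FALSE, FALSE),
    row("logs", -4, 0.5, FALSE, FALSE))
}

.in_interval <- function(x, lo, hi, lo_open, hi_open) {
  above <- if (isTRUE(lo_open)) x > lo else x >= lo
  below <- if (isTRUE(hi_open)) x < hi else x <= hi
  above & below
}

.classify_one <- function(value, r) {
  if (.in_interval(value, r$excellent_lo, r$excellent_hi,
                   r$excellent_lo_open, r$excellent_hi_open)) {
    "excellent"
  } else if (r$has_medium &&
             .in_interval(value, r$medium_lo, r$medium_hi,
                          r$medium_lo_open, r$medium_hi_open)) {
    "medium"
  } else {
    "fail"
  }
}

#' Classify one property profile
#'
#' Classes each of the ten properties as excellent, medium or fail against
#' a range table; the overall verdict passes when no property fails (i.e.
#' every property is at least in its medium range) and the percent-
#' excellent score is `100 * (#excellent) / 10`.
#'
#' @param profile named list, one-row data.frame or named numeric vector
#'   with entries `caco2, f20, pgp_sub, pgp_inh, vd, t_half, fdamdd, sas,
#'   logp, logs`.
#' @param ranges a range table (default [default_range_table()]).
#' @return object of class `screen_verdict`: per-property `classes`,
#'   `overall_pass` and `pct_excellent`.
#' @examples
#' p <- list(caco2 = -4.5, f20 = 0.1, pgp_sub = 0.2, pgp_inh = 0.1,
#'           vd = 1, t_half = 0.5, fdamdd = 0.2, sas = 3, logp = 2,
#'           logs = -2)
#' classify_properties(p)
#' @export
classify_properties <- function(profile, ranges = default_range_table()) {
  profile <- as.list(profile)
  miss <- setdiff(ranges$property, names(profile))
  if (length(miss) > 0L) {
    stop_data("missing propert", if (length(miss) > 1) "ies: " else "y: ",
              paste(miss, collapse = ", "))
  }
  vals <- vapply(ranges$property, function(p) as.numeric(profile[[p]]),
                 numeric(1))
  if (!all(is.finite(vals))) stop_data("non-finite property value")
  classes <- vapply(seq_len(nrow(ranges)),
                    function(i) .classify_one(vals[i], ranges[i, ]),
                    character(1))
  names(classes) <- ranges$property
  structure(list(classes = classes,
                 overall_pass = !any(classes == "fail"),
                 pct_excellent = 100 * mean(classes == "excellent"),
                 id = profile$id %||% NA_character_),
            class = "screen_verdict")
}

#' @export
print.screen_verdict <- function(x, ...) {
  cat("Screen verdict", if (!is.na(x$id)) paste0("(", x$id, ")"), ":",
      if (x$overall_pass) "PASS" else "FAIL", "-",
      x$pct_excellent, "% excellent\n")
  print(x$classes)
  invisible(x)
}

#' Classify a table of property profiles
#'
#' Row-wise [classify_properties()] over a profile table.
#'
#' @param profiles data.frame with an `id` column and the ten property
#'   columns.
#' @inheritParams classify_properties
#' @return data.frame with `id`, one class column per property,
#'   `overall_pass` and `pct_excellent`.
#' @export
screen_profiles <- function(profiles, ranges = default_range_table()) {
  if (!is.data.frame(profiles) || !"id" %in% names(profiles)) {
    stop_data("profiles must be a data.frame with an 'id' column")
  }
  verdicts <- lapply(seq_len(nrow(profiles)), function(i) {
    classify_properties(profiles[i, , drop = FALSE], ranges)
  })
  cls <- do.call(rbind, lapply(verdicts, function(v) {
    as.data.frame(as.list(v$classes), stringsAsFactors = FALSE)
  }))
  if (is.null(cls)) {
    cls <- as.data.frame(matrix(character(0), 0L, nrow(ranges),
                                dimnames = list(NULL, ranges$property)))
  }
  data.frame(id = as.character(profiles$id), cls,
             overall_pass = vapply(verdicts, `[[`, logical(1), "overall_pass"),
             pct_excellent = vapply(verdicts, `[[`, numeric(1),
                                    "pct_excellent"),
             stringsAsFactors = FALSE)
}

#' Multi-target binding-affinity filter
#'
#' A candidate passes when it binds all transporter targets tightly
#' (strictly below `active_cut` kcal/mol on each of DAT, NET and SERT) and
#' the hERG channel weakly (strictly above `herg_cut` kcal/mol), the
#' standard potency/cardiotoxicity trade-off.
#'
#' @param panel data.frame with kcal/mol columns for every transporter
#'   target and for hERG (see [predict_panel()]).
#' @param transporters transporter column names (default DAT, NET, SERT).
#' @param herg hERG column name.
#' @param active_cut activity threshold (default -9.54, Ki = 0.1 uM).
#' @param herg_cut safety threshold (default -8.18, Ki = 1 uM).
#' @return logical vector, one verdict per row of `panel`.
#' @export
affinity_filter <- function(panel, transporters = c("DAT", "NET", "SERT"),
                            herg = "hERG", active_cut = -9.54,
                            herg_cut = -8.18) {
  miss <- setdiff(c(transporters, herg), names(panel))
  if (length(miss) > 0L) {
    stop_data("panel lacks column(s): ", paste(miss, collapse = ", "))
  }
  pass <- rep(TRUE, nrow(panel))
  for (t in transporters) pass <- pass & panel[[t]] < active_cut
  pass & panel[[herg]] > herg_cut
}

#' Lipinski's rule-of-five filter
#'
#' Oral drug-likeness: molecular weight <= 500 Da, log P <= 5, at most 5
#' hydrogen-bond donors and at most 10 acceptors, all boundaries inclusive.
#'
#' @param mols data.frame with columns `mw`, `logp`, `nhd`, `nha`.
#' @return data.frame of per-criterion logical flags (`mw_ok`, `logp_ok`,
#'   `nhd_ok`, `nha_ok`) and the conjunction `pass`.
#' @export
lipinski_filter <- function(mols) {
  mols <- as.data.frame(mols)
  miss <- setdiff(c("mw", "logp", "nhd", "nha"), names(mols))
  if (length(miss) > 0L) {
    stop_data("missing descriptor column(s): ", paste(miss, collapse = ", "))
  }
  out <- data.frame(mw_ok = mols$mw <= 500,
                    logp_ok = mols$logp <= 5,
                    nhd_ok = mols$nhd <= 5,
                    nha_ok = mols$nha <= 10)
  out$pass <- out$mw_ok & out$logp_ok & out$nhd_ok & out$nha_ok
  out
}

#' Novelty filter against the reference compounds
#'
#' A candidate is novel when its cosine similarity to every reference
#' latent vector is strictly below `max_sim`; candidates too close to a
#' reference are rediscoveries, not leads.
#'
#' @param candidates numeric matrix of candidate latent vectors (rows), or
#'   a data.frame carrying `z0..z{d-1}` columns.
#' @param refs a [reference_set()] or numeric matrix of reference vectors.
#' @param max_sim similarity ceiling (default 0.5).
#' @return logical vector, one verdict per candidate.
#' @export
novelty_filter <- function(candidates, refs, max_sim = 0.5) {
  if (is.data.frame(candidates)) candidates <- latent_matrix(candidates)
  ref_mat <- if (inherits(refs, "reference_set")) refs$vectors else as.matrix(refs)
  sims <- similarity_matrix(as.matrix(candidates), ref_mat)
  apply(sims < max_sim, 1L, all)
}

#' Rank screened leads by percent-excellent score
#'
#' Keeps the overall-passing candidates and orders them by
#' `pct_excellent` descending, ties broken by `id` ascending.
#'
#' @param verdicts data.frame from [screen_profiles()] (needs `id`,
#'   `overall_pass`, `pct_excellent`).
#' @return the passing rows, ranked.
#' @export
rank_leads <- function(verdicts) {
  need <- c("id", "overall_pass", "pct_excellent")
  miss <- setdiff(need, names(verdicts))
  if (length(miss) > 0L) {
    stop_data("verdict table lacks column(s): ", paste(miss, collapse = ", "))
  }
  out <- verdicts[verdicts$overall_pass, , drop = FALSE]
  out[order(-out$pct_excellent, out$id), , drop = FALSE]
}
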