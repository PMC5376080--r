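# Post-processing: dose results, percent-depth-dose curves, conversion
# coefficients F = Dd/Dt for non-targeted tissues, source comparison, and
# dispersed-dose application under fractionation schedules.

#' Per-organ dose result
#'
#' @param doses Named numeric vector: organ -> dose per source photon
#'   (aGy/photon).
#' @param rel_errors Named numeric vector of tally relative errors
#'   (defaults to 0).
#' @param position Irradiation-position label (e.g. "P4").
#' @param source_label Source mode label.
#' @return A \code{dose_result}.
#' @export
dose_result <- function(doses, rel_errors = NULL, position = NA_character_,
                        source_label = NA_character_) {
  if (is.null(names(doses)) || any(!nzchar(names(doses))))
    stop("doses must be named by organ")
  if (any(doses < 0)) stop("doses must be non-negative")
  if (is.null(rel_errors)) rel_errors <- stats::setNames(
    rep(0, length(doses)), names(doses))
  structure(list(doses = doses, rel_errors = rel_errors[names(doses)],
                 position = position, source_label = source_label),
            class = "dose_result")
}

#' Extract a dose_result from a tally_result
#'
#' @param tally A \code{tally_result} from \code{run()}.
#' @param position Irradiation-position label.
#' @param source_label Source mode label.
#' @return A \code{dose_result} in aGy/photon.
#' @export
as_dose_result <- function(tally, position = NA_character_,
                           source_label = NA_character_) {
  d <- tally$doses
  dose_result(stats::setNames(d$dose_agy, d$organ),
              stats::setNames(d$rel_error, d$organ),
              position, source_label)
}

#' Compute conversion coefficients F = Dd/Dt
#'
#' The conversion coefficient of a non-targeted tissue is its dose
#' divided by the dose in the targeted tissue of the same irradiation;
#' F of the target itself is 1 exactly, and F is invariant under any
#' uniform rescaling of the doses (it is independent of fluence
#' normalization). Relative errors combine in quadrature.
#'
#' @param doses A \code{dose_result}.
#' @param target Target organ name (its dose must be positive).
#' @return A \code{conversion_table}: data.frame(position, organ, F,
#'   rel_error) plus provenance attributes.
#' @export
compute_conversion_coefficients <- function(doses, target) {
  stopifnot(inherits(doses, "dose_result"))
  dt <- doses$doses[target]
  if (is.na(dt) || length(dt) == 0)
    stop("conversion undefined: target organ '", target, "' absent")
  if (dt <= 0) stop("conversion undefined: target dose is zero")
  f <- doses$doses / as.numeric(dt)
  f[target] <- 1
  re <- sqrt(doses$rel_errors^2 + doses$rel_errors[[target]]^2)
  re[target] <- 0
  tab <- data.frame(position = doses$position, organ = names(f),
                    F = as.numeric(f), rel_error = as.numeric(re),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(tab, class = c("conversion_table", "data.frame"),
            target = target, source_label = doses$source_label)
}

#' Build a conversion table from explicit F values
#'
#' For applying printed coefficients (or merging several runs) without a
#' simulation.
#'
#' @param position Irradiation-position label.
#' @param F Named numeric vector organ -> F (all >= 0).
#' @param target Target organ; its F must be 1 (added if absent).
#' @param rel_error Optional named relative errors (default 0).
#' @return A \code{conversion_table}.
#' @export
conversion_table <- function(position, F, target, rel_error = NULL) {
  if (any(F < 0)) stop("F values must be non-negative")
  if (!target %in% names(F)) F <- c(stats::setNames(1, target), F)
  if (F[[target]] != 1) stop("F of the target organ must be 1")
  if (is.null(rel_error)) rel_error <- stats::setNames(rep(0, length(F)),
                                                       names(F))
  tab <- data.frame(position = position, organ = names(F),
                    F = as.numeric(F),
                    rel_error = as.numeric(rel_error[names(F)]),
                    row.names = NULL, stringsAsFactors = FALSE)
  tab$rel_error[is.na(tab$rel_error)] <- 0
  structure(tab, class = c("conversion_table", "data.frame"),
            target = target, source_label = NA_character_)
}

#' Fractionation schedule
#'
#' @param total_gy Prescribed total dose to the target (Gy).
#' @param n_fractions Number of fractions.
#' @param per_day Fractions per day (optional).
#' @param days Duration in days (optional). When both per_day and days
#'   are given, n_fractions must equal per_day * days.
#' @return A \code{fractionation_schedule}.
#' @export
fractionation_schedule <- function(total_gy, n_fractions, per_day = NULL,
                                   days = NULL) {
  if (total_gy <= 0 || n_fractions <= 0) stop("schedule values must be positive")
  if (!is.null(per_day) && !is.null(days)) {
    if (per_day <= 0 || days <= 0) stop("schedule values must be positive")
    if (per_day * days != n_fractions)
      stop("inconsistent schedule: ", n_fractions, " fractions != ",
           per_day, " per day x ", days, " days")
  }
  structure(list(total_gy = total_gy, n_fractions = n_fractions,
                 per_day = per_day, days = days),
            class = "fractionation_schedule")
}

#' Apply conversion coefficients to a prescribed schedule
#'
#' Dispersed dose per organ = F x prescribed total dose; linear in the
#' prescription and bounded by it wherever F <= 1. Per-fraction doses are
#' total/n_fractions.
#'
#' @param table A \code{conversion_table}.
#' @param schedule A \code{fractionation_schedule}.
#' @param position Irradiation-position label to select from the table.
#' @return data.frame(organ, F, dispersed_gy, per_fraction_gy,
#'   percent_of_target).
#' @export
apply_conversion <- function(table, schedule, position = NULL) {
  stopifnot(inherits(table, "conversion_table"),
            inherits(schedule, "fractionation_schedule"))
  tab <- as.data.frame(table)
  if (!is.null(position)) {
    tab <- tab[tab$position == position, ]
    if (nrow(tab) == 0) stop("position not in table: ", position)
  }
  data.frame(organ = tab$organ, F = tab$F,
             dispersed_gy = tab$F * schedule$total_gy,
             per_fraction_gy = tab$F * schedule$total_gy /
               schedule$n_fractions,
             percent_of_target = 100 * tab$F,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Percent-depth-dose curve
#'
#' PDD(i) = 100 x D(i)/Dmax along the beam central axis.
#'
#' @param depth_doses data.frame with columns \code{depth_cm} and
#'   \code{dose} (any consistent unit), or two vectors via \code{dose}.
#' @param dose Optional dose vector when \code{depth_doses} is a depth
#'   vector.
#' @return A \code{pdd_curve}: data.frame(depth_cm, pdd) with attribute
#'   \code{d_max}.
#' @export
compute_pdd <- function(depth_doses, dose = NULL) {
  if (!is.null(dose)) depth_doses <- data.frame(depth_cm = depth_doses,
                                                dose = dose)
  if (nrow(depth_doses) < 2) stop("need at least 2 depth bins")
  if (all(depth_doses$dose == 0)) stop("all depth doses are zero")
  if (any(depth_doses$dose < 0)) stop("negative dose")
  dmax_i <- which.max(depth_doses$dose)
  out <- data.frame(depth_cm = depth_doses$depth_cm,
                    pdd = 100 * depth_doses$dose /
                      depth_doses$dose[dmax_i])
  structure(out, class = c("pdd_curve", "data.frame"),
            d_max = depth_doses$depth_cm[dmax_i])
}

#' PDD curve from a water-benchmark tally
#'
#' @param tally \code{tally_result} from running the water-phantom
#'   benchmark scenario.
#' @return A \code{pdd_curve} with per-bin relative errors attached.
#' @export
pdd_from_tally <- function(tally) {
  d <- tally$doses[grepl("^pdd\\.", tally$doses$cell), ]
  depth <- as.numeric(sub("depth_", "", d$organ))
  cur <- compute_pdd(data.frame(depth_cm = depth, dose = d$dose_mev_g))
  cur$rel_error <- d$rel_error
  cur
}

#' Summary of an energy-binned spectrum tally
#'
#' @param spectrum data.frame(e_lo, e_hi, counts) (from \code{run()}) or
#'   a \code{beam_spectrum}.
#' @return list(mean_mev, table) — the table is normalized to unit sum.
#' @export
spectrum_summary <- function(spectrum) {
  if (inherits(spectrum, "beam_spectrum")) {
    if (spectrum$mode == "lines")
      spectrum <- data.frame(e_lo = spectrum$energies,
                             e_hi = spectrum$energies,
                             counts = spectrum$probs)
    else
      spectrum <- data.frame(e_lo = spectrum$edges[-length(spectrum$edges)],
                             e_hi = spectrum$edges[-1],
                             counts = spectrum$probs)
  }
  tot <- sum(spectrum$counts)
  if (tot <= 0) stop("zero total counts in spectrum")
  p <- spectrum$counts / tot
  mid <- (spectrum$e_lo + spectrum$e_hi) / 2
  list(mean_mev = sum(mid * p),
       table = data.frame(e_lo = spectrum$e_lo, e_hi = spectrum$e_hi,
                          probability = p))
}

#' Compare per-photon doses from two sources
#'
#' Per-organ ratio (first/second) at matched per-source-photon
#' normalization, with errors combined in quadrature; used to contrast a
#' collimated accelerator beam with an isotropic point source.
#'
#' @param doses_a,doses_b \code{dose_result}s sharing an organ set.
#' @return data.frame(organ, dose_a, dose_b, ratio, rel_error).
#' @export
compare_sources <- function(doses_a, doses_b) {
  organs <- intersect(names(doses_a$doses), names(doses_b$doses))
  if (length(organs) == 0) stop("disjoint organ sets")
  a <- doses_a$doses[organs]; b <- doses_b$doses[organs]
  data.frame(organ = organs, dose_a = as.numeric(a), dose_b = as.numeric(b),
             ratio = as.numeric(ifelse(b > 0, a / b, NA)),
             rel_error = sqrt(doses_a$rel_errors[organs]^2 +
                                doses_b$rel_errors[organs]^2),
             row.names = NULL, stringsAsFactors = FALSE)
}
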