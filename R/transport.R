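# The Monte Carlo run: history loop (in the compiled kernel), batch
# statistics, and the deterministic parallel contract. Every history h of
# a run draws from its own RNG stream keyed by (seed, h), so tallies are
# bit-identical however histories are partitioned across batches or
# workers.

PHYS_GRID_N <- 256L

#' Run configuration
#'
#' @param n_histories Total primary photons (>= n_batches).
#' @param n_batches Statistical batches (default 20, >= 2).
#' @param seed Integer RNG seed.
#' @param cutoff_mev Photon cutoff; remaining energy is deposited locally
#'   (default 0.01, the library minimum).
#' @param analog Analog transport (no implicit capture / roulette);
#'   guarantees exact per-history energy balance.
#' @param rr_threshold,rr_survival Russian-roulette weight threshold and
#'   survival weight (implicit-capture mode).
#' @param workers Parallel workers (forked); results are independent of
#'   this value.
#' @param target_rel_error Optional early-stop target for the largest
#'   tally relative error (e.g. 0.004).
#' @param max_segments Per-track segment guard.
#' @return A \code{run_config}.
#' @export
run_config <- function(n_histories, n_batches = 20L, seed = 1L,
                       cutoff_mev = 0.01, analog = FALSE,
                       rr_threshold = 0.01, rr_survival = 0.1,
                       workers = 1L, target_rel_error = NULL,
                       max_segments = 10000L) {
  n_histories <- as.integer(n_histories)
  n_batches <- as.integer(n_batches)
  if (n_batches < 2) stop("need at least 2 batches")
  if (n_histories < n_batches) stop("n_histories must be >= n_batches")
  if (cutoff_mev < XS_EMIN) stop("cutoff below the cross-section grid")
  structure(list(n_histories = n_histories, n_batches = n_batches,
                 seed = as.integer(seed), cutoff_mev = cutoff_mev,
                 analog = analog, rr_threshold = rr_threshold,
                 rr_survival = rr_survival, workers = as.integer(workers),
                 target_rel_error = target_rel_error,
                 max_segments = as.integer(max_segments)),
            class = "run_config")
}

.phys_cache <- new.env(parent = emptyenv())

# Mean Compton deposited-energy fraction on the dense grid (quadrature).
mean_compton_deposit_frac <- function(energies) {
  key <- paste0("dep_", length(energies), "_", signif(energies[1], 8))
  if (is.null(.phys_cache[[key]])) {
    .phys_cache[[key]] <- vapply(
      energies, function(e) 1 - kn_moments(e)$mean_scatter_frac, 0)
  }
  .phys_cache[[key]]
}

# Build the dense per-material attenuation/heating tables for the kernel.
compile_physics <- function(mat_names, lib = material_library()) {
  egrid <- exp(seq(log(XS_EMIN), log(XS_EMAX), length.out = PHYS_GRID_N))
  dep <- mean_compton_deposit_frac(egrid)
  nm <- length(mat_names)
  mu_pe <- mu_inc <- mu_pair <- kappa <- matrix(0, nm, PHYS_GRID_N)
  for (i in seq_len(nm)) {
    m <- lib[[mat_names[i]]]
    if (is.null(m)) stop("unknown material: ", mat_names[i])
    if (length(m$composition) == 0) next
    mu_pe[i, ] <- mu_total(m, egrid, "photoelectric")
    mu_inc[i, ] <- mu_total(m, egrid, "incoherent")
    mu_pair[i, ] <- mu_total(m, egrid, "pair")
    kappa[i, ] <- mu_pe[i, ] * egrid + mu_inc[i, ] * egrid * dep +
      mu_pair[i, ] * pmax(0, egrid - PAIR_THRESHOLD_MEV)
  }
  list(loge0 = log(XS_EMIN),
       dloge = (log(XS_EMAX) - log(XS_EMIN)) / (PHYS_GRID_N - 1),
       mu_pe = mu_pe, mu_inc = mu_inc, mu_pair = mu_pair, kappa = kappa,
       mat_names = mat_names, lib = lib)
}

# Resolve cells -> material rows, density scale factors, masses.
compile_cells <- function(scn, lib = material_library()) {
  cells <- scn$model$cells
  mat_names <- unique(vapply(cells, `[[`, "", "material"))
  phys <- compile_physics(mat_names, lib)
  idx <- match(vapply(cells, `[[`, "", "material"), mat_names) - 1L
  scale <- vapply(cells, function(cl) {
    if (is.null(cl$density_override)) return(1)
    d0 <- lib[[cl$material]]$density
    if (d0 <= 0) stop("density override on a vacuum cell")
    cl$density_override / d0
  }, 0)
  density <- vapply(cells, function(cl) {
    d0 <- lib[[cl$material]]$density
    if (is.null(cl$density_override)) d0 else cl$density_override
  }, 0)
  list(phys = phys, cell_mat = as.integer(idx), cell_mu_scale = scale,
       density = density,
       volume = vapply(cells, `[[`, 0, "volume"),
       tally = vapply(cells, `[[`, FALSE, "tally"),
       organ = vapply(cells, function(cl)
         if (is.null(cl$organ)) NA_character_ else cl$organ, ""))
}

source_kernel_args <- function(source) {
  type <- if (source$mode == "monoenergetic-point") 0L
          else if (!is.null(source$half_angle_deg) &&
                   source$half_angle_deg > 0) 1L else 2L
  sp <- source$spectrum
  if (sp$mode == "lines") {
    spec_mode <- 0L; spec_e <- sp$energies; cdf <- cumsum(sp$probs)
  } else {
    spec_mode <- 1L; spec_e <- sp$edges; cdf <- cumsum(sp$probs)
  }
  cdf[length(cdf)] <- 1
  list(type = type, pos = source$position, axis = source$axis,
       cos_half = if (type == 1L)
         cos(source$half_angle_deg * pi / 180) else 1,
       spec_mode = spec_mode, spec_e = spec_e, spec_cdf = cdf)
}

run_batch_raw <- function(scn, cc, src, config, hist_start, n_hist,
                          spec_surf = -1L, spec_edges = numeric()) {
  g <- scn$model$compiled
  cpp_run_batch(g$surf_coef, g$tokens, g$tok_offset, g$tok_len, g$world,
                cc$cell_mat, cc$cell_mu_scale,
                cc$phys$loge0, cc$phys$dloge,
                cc$phys$mu_pe, cc$phys$mu_inc, cc$phys$mu_pair,
                cc$phys$kappa,
                src$type, src$pos, src$axis, src$cos_half,
                src$spec_mode, src$spec_e, src$spec_cdf,
                config$cutoff_mev, config$analog, config$rr_threshold,
                config$rr_survival, config$max_segments,
                spec_surf, spec_edges,
                as.numeric(hist_start), as.integer(n_hist),
                as.numeric(config$seed))
}

#' Run a single photon history
#'
#' Transports one primary (history \code{history_index} of the stream
#' keyed by \code{seed}) and returns its per-cell deposited energy,
#' escaped energy and emitted energy — the per-history energy balance
#' emitted = deposited + escaped (+ expected rouletted weight) holds to
#' 1e-9 relative in analog mode.
#'
#' @param scenario A \code{scenario}.
#' @param history_index Zero-based history index.
#' @param seed Stream seed.
#' @param analog Analog transport (default TRUE).
#' @return list(deposited — named by cell, escaped, emitted, lost).
#' @export
run_history <- function(scenario, history_index = 0, seed = 1,
                        analog = TRUE) {
  config <- run_config(n_histories = 2, n_batches = 2, seed = seed,
                       analog = analog)
  cc <- compile_cells(scenario)
  src <- source_kernel_args(scenario$source)
  r <- run_batch_raw(scenario, cc, src, config, history_index, 1L)
  dep <- r$coll
  names(dep) <- names(scenario$model$cells)
  list(deposited = dep, escaped = r$escaped, emitted = r$emitted,
       rouletted = r$rouletted, lost = r$lost)
}

#' Run a Monte Carlo simulation
#'
#' Transports \code{config$n_histories} primaries through the scenario in
#' \code{config$n_batches} statistical batches, optionally on several
#' forked workers. Tallies are normalized per source photon; identical
#' (scenario, seed, n_histories, n_batches) give bit-identical results
#' for any worker count.
#'
#' @param scenario A \code{scenario}.
#' @param config A \code{run_config}.
#' @param spectrum_surface Optional surface id on which to tally the
#'   crossing-energy spectrum.
#' @param spectrum_edges Energy bin edges (MeV) for that tally.
#' @return A \code{tally_result}: \code{$doses} (per tally region, MeV/g
#'   and aGy per source photon with relative errors from batch means, for
#'   both the collision and track-length estimators), \code{$totals},
#'   \code{$batch_means}, \code{$spectrum}.
#' @export
run <- function(scenario, config, spectrum_surface = NULL,
                spectrum_edges = numeric()) {
  stopifnot(inherits(scenario, "scenario"), inherits(config, "run_config"))
  cc <- compile_cells(scenario)
  src <- source_kernel_args(scenario$source)
  g <- scenario$model$compiled
  spec_surf <- -1L
  if (!is.null(spectrum_surface)) {
    spec_surf <- match(spectrum_surface, g$surf_ids) - 1L
    if (is.na(spec_surf)) stop("unknown spectrum surface: ", spectrum_surface)
    if (length(spectrum_edges) < 2) stop("need spectrum bin edges")
  }

  nb <- config$n_batches
  base <- config$n_histories %/% nb
  sizes <- rep(base, nb)
  sizes[nb] <- sizes[nb] + config$n_histories - base * nb
  starts <- cumsum(c(0, sizes[-nb]))

  do_batch <- function(b)
    run_batch_raw(scenario, cc, src, config, starts[b], sizes[b],
                  spec_surf, spectrum_edges)

  early_stop <- !is.null(config$target_rel_error) && config$workers == 1L
  if (config$workers > 1L &&
      .Platform$OS.type == "unix" && !early_stop) {
    res <- parallel::mclapply(seq_len(nb), do_batch,
                              mc.cores = config$workers)
  } else {
    res <- vector("list", nb)
    for (b in seq_len(nb)) {
      res[[b]] <- do_batch(b)
      if (early_stop && b >= 2) {
        part <- summarize_batches(res[seq_len(b)], sizes[seq_len(b)], cc,
                                  scenario)
        re <- part$doses$rel_error[part$doses$dose_mev_g > 0]
        if (length(re) && all(is.finite(re)) &&
            max(re) <= config$target_rel_error) {
          res <- res[seq_len(b)]
          sizes <- sizes[seq_len(b)]
          break
        }
      }
    }
  }
  out <- summarize_batches(res, sizes, cc, scenario)
  out$config <- config
  out$spectrum <- if (spec_surf >= 0)
    data.frame(e_lo = spectrum_edges[-length(spectrum_edges)],
               e_hi = spectrum_edges[-1],
               counts = Reduce(`+`, lapply(res, `[[`, "spec_counts")))
    else NULL
  n_lost <- sum(vapply(res, `[[`, 0, "lost"))
  if (n_lost > max(1, 1e-6 * config$n_histories))
    stop("lost-particle tolerance exceeded: ", n_lost, " histories lost")
  out
}

summarize_batches <- function(res, sizes, cc, scenario) {
  nb <- length(res)
  cells <- names(scenario$model$cells)
  coll <- vapply(res, `[[`, numeric(length(cells)), "coll")
  tl <- vapply(res, `[[`, numeric(length(cells)), "tl")
  bm_coll <- t(coll) / sizes        # batch means: MeV per source photon
  bm_tl <- t(tl) / sizes
  colnames(bm_coll) <- colnames(bm_tl) <- cells
  n_done <- sum(vapply(res, `[[`, 0, "n_done"))
  mass <- cc$volume * cc$density
  mean_coll <- rowSums(coll) / sum(sizes)
  mean_tl <- rowSums(tl) / sum(sizes)

  keep <- which(cc$tally)
  re_coll <- vapply(keep, function(i)
    estimate_relative_error(bm_coll[, i]), 0)
  re_tl <- vapply(keep, function(i) estimate_relative_error(bm_tl[, i]), 0)
  dmg <- ifelse(is.finite(mass[keep]) & mass[keep] > 0,
                mean_coll[keep] / mass[keep], NA_real_)   # massless: fluence-only tally
  doses <- data.frame(
    cell = cells[keep],
    organ = cc$organ[keep],
    mass_g = mass[keep],
    dose_mev_g = dmg,
    rel_error = re_coll,
    dose_agy = dmg * MEV_PER_G_TO_GY * 1e18,
    dose_tl_mev_g = ifelse(is.finite(mass[keep]) & mass[keep] > 0,
                           mean_tl[keep] / mass[keep], NA_real_),
    rel_error_tl = re_tl,
    row.names = NULL, stringsAsFactors = FALSE)
  totals <- list(
    emitted = sum(vapply(res, `[[`, 0, "emitted")),
    escaped = sum(vapply(res, `[[`, 0, "escaped")),
    deposited = sum(coll),
    rouletted = sum(vapply(res, `[[`, 0, "rouletted")),
    uncollided = sum(vapply(res, `[[`, 0, "uncollided")),
    lost = sum(vapply(res, `[[`, 0, "lost")),
    n_histories = sum(sizes), n_done = n_done, n_batches = nb)
  fluence <- rowSums(vapply(res, `[[`, numeric(length(cells)), "path")) /
    sum(sizes)
  structure(list(doses = doses, totals = totals,
                 batch_means = bm_coll, batch_means_tl = bm_tl,
                 cell_track_per_photon = stats::setNames(fluence, cells),
                 cell_volume = stats::setNames(cc$volume, cells),
                 label = scenario$label, seed = NA),
            class = "tally_result")
}

#' Relative error of a tally from batch means
#'
#' Standard batch statistics: one standard error of the mean
#' (sd(batch means)/sqrt(n)) divided by the mean. Undefined (NA) for a
#' zero mean.
#'
#' @param batch_means Numeric vector of per-batch means (>= 2 values).
#' @param target Convergence target (default 0.004, i.e. 0.4 percent).
#' @return The relative error; attribute \code{converged} says whether it
#'   is at or below \code{target}.
#' @export
estimate_relative_error <- function(batch_means, target = 0.004) {
  if (length(batch_means) < 2) stop("need at least 2 batches")
  m <- mean(batch_means)
  if (m == 0) {
    re <- NA_real_
  } else {
    re <- stats::sd(batch_means) / sqrt(length(batch_means)) / m
  }
  structure(re, converged = is.finite(re) && re <= target)
}

#' @export
print.tally_result <- function(x, ...) {
  cat(sprintf("<tally_result> %s: %d histories, %d tally regions\n",
              x$label, x$totals$n_histories, nrow(x$doses)))
  d <- x$doses
  d$dose_agy <- signif(d$dose_agy, 3)
  d$rel_error <- signif(d$rel_error, 3)
  print(utils::head(d[c("organ", "dose_agy", "rel_error")], 15))
  invisible(x)
}
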