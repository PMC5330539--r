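#' Full multi-scale analysis of one raster
#'
#' Runs the complete characterisation pipeline on a spike raster:
#' population firing rates, excitatory ISI irregularity, pairwise
#' synchrony, spectral peak of the excitatory population activity,
#' avalanche extraction with power-law fit and distance \eqn{D}, and
#' pattern entropy/efficiency in the requested scenarios and resting
#' energies.
#'
#' @param x a \code{\link{SpikeData}} raster.
#' @param n_pairs pairs sampled for the synchrony index.
#' @param delta_t avalanche bin width (ms).
#' @param window pattern window (ms).
#' @param n neurons per pattern subset.
#' @param n_samples pattern subsets.
#' @param scenarios pattern scenarios to evaluate.
#' @param r_values resting energies at which the efficiency is reported.
#' @param seed seed for the stochastic analysis steps (pair and subset
#'   sampling).
#' @return one-row data.frame with named columns (\code{v_E},
#'   \code{v_I}, \code{cv_E}, \code{synchrony}, \code{peak_freq},
#'   \code{peak_power}, \code{D}, \code{alpha}, and per scenario
#'   \code{H_<scenario>} plus \code{eta_<scenario>_r<r>} columns).
#' @export
analyzeRaster <- function(x, n_pairs = 2000, delta_t = 0.1, window = 20,
                          n = 40, n_samples = 100,
                          scenarios = c("binary", "analog"),
                          r_values = c(0, 0.005, 0.1), seed = 1) {
  stopifnot(is(x, "SpikeData"))
  out <- data.frame(
    v_E = firingRate(x, "E"),
    v_I = if (any(x@label == "I")) firingRate(x, "I") else NA_real_,
    cv_E = meanISICV(x, "E"),
    synchrony = synchronyIndex(x, "E", n_pairs = n_pairs, seed = seed)
  )
  spec <- spectrumPeak(populationActivity(x, bin = 1, population = "E"))
  out$peak_freq <- spec@peakFreq
  out$peak_power <- spec@peakPower
  av <- extractAvalanches(x, delta_t = delta_t)
  fit <- tryCatch(fitPowerLaw(av), error = function(e) NULL)
  out$n_avalanches <- length(av@sizes)
  out$alpha <- if (is.null(fit)) NA_real_ else fit@exponent
  out$D <- if (is.null(fit)) NA_real_ else fit@distance
  for (scn in scenarios) {
    ens <- makePatterns(x, window = window, n = n, scenario = scn,
                        n_samples = n_samples, seed = seed + 1)
    rpt0 <- patternEfficiency(ens, r = r_values[1])
    out[[paste0("H_", scn)]] <- rpt0@H
    out[[paste0("m_", scn)]] <- rpt0@m
    out[[paste0("mn_", scn)]] <- rpt0@mn
    for (r in r_values) {
      rpt <- patternEfficiency(ens, r = r)
      out[[paste0("eta_", scn, "_r", r)]] <- rpt@etaSim
    }
  }
  out
}

#' Sweep the synaptic-decay parameter space
#'
#' Simulates the network and runs \code{\link{analyzeRaster}} for every
#' cell of a (\code{tau_de}, \code{tau_di}) grid and every seed,
#' returning one row per (cell, seed).  Cells are cached as CSV files
#' keyed by their configuration when \code{cache_dir} is given, so
#' re-running a completed sweep performs no simulations; a failed cell
#' is kept as a flagged row and the sweep continues.
#'
#' @param tau_de,tau_di grid coordinates (ms); the sweep covers their
#'   Cartesian product.
#' @param duration,discard simulated and discarded time (s).
#' @param seeds one or more simulation seeds.
#' @param params_base template \code{\link{NetworkParams}}; the grid
#'   coordinates, duration and seed are substituted per cell.
#' @param cache_dir optional directory for per-cell result caching.
#' @param ... further arguments passed to \code{\link{analyzeRaster}}.
#' @return data.frame with columns \code{tau_de}, \code{tau_di},
#'   \code{seed}, \code{duration}, \code{flagged}, plus the
#'   \code{analyzeRaster} columns; attribute \code{cells_simulated}
#'   counts the simulations actually performed.
#' @examples
#' \donttest{
#' sw <- runSweep(tau_de = c(4, 6), tau_di = c(6, 10), duration = 5,
#'                seeds = 1)
#' sw[, c("tau_de", "tau_di", "v_E", "synchrony")]
#' }
#' @export
runSweep <- function(tau_de = c(2, 3, 4, 5, 6),
                     tau_di = c(6, 8, 10, 12, 14),
                     duration = 50, discard = 1, seeds = 1L,
                     params_base = networkParams(),
                     cache_dir = NULL, ...) {
  grid <- expand.grid(tau_de = tau_de, tau_di = tau_di,
                      seed = as.integer(seeds))
  n_sim <- 0L
  rows <- vector("list", nrow(grid))
  if (nrow(grid) == 0) {
    out <- data.frame(tau_de = numeric(), tau_di = numeric(),
                      seed = integer(), duration = numeric(),
                      flagged = logical())
    attr(out, "cells_simulated") <- 0L
    return(out)
  }
  for (g in seq_len(nrow(grid))) {
    p <- params_base
    p@tau_de <- grid$tau_de[g]
    p@tau_di <- grid$tau_di[g]
    p@duration <- duration
    p@discard <- discard
    p@seed <- grid$seed[g]
    key <- .cellKey(p, ...)
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, paste0("critcap-cell-", key, ".csv")) else NULL
    row <- NULL
    if (!is.null(cache_file) && file.exists(cache_file))
      row <- utils::read.csv(cache_file)
    if (is.null(row)) {
      row <- tryCatch({
        raster <- simulateNetwork(p)
        n_sim <- n_sim + 1L
        cbind(data.frame(tau_de = p@tau_de, tau_di = p@tau_di,
                         seed = p@seed, duration = duration,
                         flagged = FALSE),
              analyzeRaster(raster, seed = p@seed, ...))
      }, error = function(e) {
        warning("cell (", p@tau_de, ", ", p@tau_di, ") seed ", p@seed,
                " failed: ", conditionMessage(e))
        data.frame(tau_de = p@tau_de, tau_di = p@tau_di, seed = p@seed,
                   duration = duration, flagged = TRUE)
      })
      if (!is.null(cache_file) && !row$flagged[1]) {
        if (!dir.exists(cache_dir))
          dir.create(cache_dir, recursive = TRUE)
        utils::write.csv(row, cache_file, row.names = FALSE)
      }
    }
    rows[[g]] <- row
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cc in setdiff(all_cols, names(r))) r[[cc]] <- NA
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  attr(out, "cells_simulated") <- n_sim
  out
}

# deterministic cache key from the full cell configuration
.cellKey <- function(p, ...) {
  extra <- list(...)
  vals <- c(p@N, p@ratio_EI, p@C, p@K_O, p@f_ex, p@g_EO, p@g_IO, p@g_EE,
            p@g_IE, p@g_EI, p@g_II, p@E_E, p@E_I, p@tau_E, p@tau_I,
            p@V_L, p@theta, p@V_reset, p@t_rp_E, p@t_rp_I, p@tau_l,
            p@tau_r, p@tau_de, p@tau_di, p@dt, p@duration, p@discard,
            p@seed, p@model_variant, p@V_mean,
            unlist(extra, use.names = FALSE))
  txt <- paste(format(vals, digits = 15), collapse = "|")
  # small rolling hash (deterministic across sessions, text-safe)
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%010d", h)
}
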