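#' Interspike-interval specifications
#'
#' An `isi_spec` is a generative description of one presynaptic unit's
#' interspike-interval (ISI) distribution. Three families are supported:
#'
#' * `isi_lognormal(rate)` — the in-vivo-like family. Purkinje cells fire
#'   with refractory-like regularity whose ISI distributions are well
#'   approximated by lognormals; across cells the ISI standard deviation
#'   follows the fitted linear relation `sd = -0.00154 + 0.583 * mean`
#'   (seconds). Given a target rate, the mean ISI is `1/rate`, the sd comes
#'   from the relation, and the natural-log parameters are obtained by
#'   moment inversion: `sigma^2 = log(1 + (sd/mean)^2)`,
#'   `mu = log(mean) - sigma^2/2`.
#' * `isi_poisson(rate)` — exponential ISIs (no refractory structure), the
#'   control against which refractory effects are measured.
#' * `isi_resampled(pool, rate)` — ISIs drawn i.i.d. with replacement from a
#'   user-supplied pool of intervals (e.g. from a real recording).
#'
#' @param rate target event rate in events/s. For the lognormal family the
#'   implied sd must be positive, which bounds the rate below
#'   `0.583/0.00154` (about 378.6 events/s).
#' @param pool numeric vector of ISI values in seconds (resampled family).
#' @return An object of class `isi_spec` with fields `family`, `rate`,
#'   `mean_isi`, `sd_isi`, and for the lognormal family `mu`, `sigma`.
#' @examples
#' s <- isi_lognormal(80)
#' c(s$mean_isi, s$sd_isi)   # 0.0125 s, 0.0057475 s
#' @export
isi_lognormal <- function(rate) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stopf("rate must be a single positive number (got %s)", format(rate))
  mean_isi <- 1 / rate
  sd_isi <- ISI_SD_INTERCEPT + ISI_SD_SLOPE * mean_isi
  if (sd_isi <= 0)
    stopf(paste0(
      "rate %.4g /s implies a nonpositive ISI sd under sd = %.5f + %.3f*mean; ",
      "admissible rates are 0 < rate < %.4g /s"),
      rate, ISI_SD_INTERCEPT, ISI_SD_SLOPE, ISI_SD_SLOPE / -ISI_SD_INTERCEPT)
  sigma2 <- log(1 + (sd_isi / mean_isi)^2)
  structure(list(
    family = "lognormal", rate = rate, mean_isi = mean_isi, sd_isi = sd_isi,
    mu = log(mean_isi) - sigma2 / 2, sigma = sqrt(sigma2)
  ), class = "isi_spec")
}

#' @rdname isi_lognormal
#' @export
isi_poisson <- function(rate) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stopf("rate must be a single positive number (got %s)", format(rate))
  structure(list(family = "poisson", rate = rate, mean_isi = 1 / rate,
                 sd_isi = 1 / rate), class = "isi_spec")
}

#' @rdname isi_lognormal
#' @export
isi_resampled <- function(pool, rate = 1 / mean(pool)) {
  pool <- as.numeric(pool)
  if (length(pool) < 2L || any(!is.finite(pool)) || any(pool <= 0))
    stopf("pool must hold at least two positive finite ISI values")
  structure(list(family = "resampled", rate = rate, mean_isi = mean(pool),
                 sd_isi = sd(pool), sample_pool = pool), class = "isi_spec")
}

#' @export
print.isi_spec <- function(x, ...) {
  cat(sprintf("ISI spec [%s]: rate %.4g /s, mean %.4g s, sd %.4g s\n",
              x$family, x$rate, x$mean_isi, x$sd_isi))
  invisible(x)
}

draw_isis <- function(spec, n) {
  switch(spec$family,
    lognormal = rlnorm(n, meanlog = spec$mu, sdlog = spec$sigma),
    poisson   = rexp(n, rate = spec$rate),
    resampled = sample(spec$sample_pool, n, replace = TRUE),
    stopf("unknown ISI family '%s'", spec$family)
  )
}

#' Spike trains
#'
#' Constructs a spike train: strictly increasing event times in seconds on
#' `[0, duration)`. An empty train is allowed.
#'
#' @param times numeric vector of event times in seconds.
#' @param duration train duration in seconds.
#' @param unit_id label for the presynaptic unit.
#' @return An object of class `spike_train` with fields `times`, `duration`,
#'   `unit_id`.
#' @export
spike_train <- function(times, duration, unit_id = "unit") {
  times <- as.numeric(times)
  if (length(times)) {
    if (any(!is.finite(times)) || any(times < 0) || any(times >= duration))
      stopf("spike times must lie in [0, duration)")
    if (any(diff(times) <= 0))
      stopf("spike times must be strictly increasing")
  }
  structure(list(times = times, duration = as.numeric(duration),
                 unit_id = unit_id), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train '%s': %d events over %.6g s (%.4g /s)\n",
              x$unit_id, length(x$times), x$duration,
              if (x$duration > 0) length(x$times) / x$duration else 0))
  invisible(x)
}

#' Generate a spike train from an ISI specification
#'
#' Event times are the cumulative sum of i.i.d. ISI draws. The first event
#' is placed at a uniform random fraction of one drawn ISI, so the train
#' starts in an approximately stationary phase rather than with an event
#' pinned at time zero. Draws come from the current R random stream; set a
#' seed (or use [assign_synchrony()], which manages per-unit substreams)
#' for reproducibility.
#'
#' @param spec an [isi_lognormal()] / [isi_poisson()] / [isi_resampled()]
#'   specification.
#' @param duration train duration in seconds (`>= 0`).
#' @param unit_id label for the unit.
#' @return A [spike_train()].
#' @examples
#' set.seed(1)
#' tr <- generate_train(isi_lognormal(80), duration = 10)
#' length(tr$times) / tr$duration   # close to 80
#' @export
generate_train <- function(spec, duration, unit_id = "unit") {
  stopifnot(inherits(spec, "isi_spec"))
  if (!is.numeric(duration) || length(duration) != 1L || duration < 0)
    stopf("duration must be a single nonnegative number")
  if (duration == 0)
    return(spike_train(numeric(0), 0, unit_id))
  first <- runif(1) * draw_isis(spec, 1L)
  times <- numeric(0)
  last <- first
  block <- max(128L, as.integer(ceiling(1.1 * duration / spec$mean_isi)))
  repeat {
    if (last >= duration) break
    isis <- draw_isis(spec, block)
    times <- c(times, last + cumsum(c(0, isis)))
    last <- times[length(times)]
  }
  spike_train(times[times < duration], duration, unit_id)
}

#' Generate a homogeneous Poisson spike train
#'
#' Exponential ISIs with mean `1/rate`; no refractory structure. `rate = 0`
#' yields an empty train.
#'
#' @param rate event rate in events/s (`>= 0`).
#' @inheritParams generate_train
#' @return A [spike_train()].
#' @export
generate_poisson_train <- function(rate, duration, unit_id = "unit") {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0)
    stopf("rate must be a single nonnegative number")
  if (rate == 0 || duration == 0)
    return(spike_train(numeric(0), duration, unit_id))
  generate_train(isi_poisson(rate), duration, unit_id)
}

# Independent L'Ecuyer-CMRG substreams derived from one master seed; stream
# i is reserved for unit i, so adding a unit never perturbs earlier units.
rng_substreams <- function(seed, n) {
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

with_rng_stream <- function(stream, expr) {
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  old_kind <- RNGkind()
  on.exit({
    # restore the generator kind first: assigning/removing .Random.seed
    # alone leaves the session's internal kind pointing at the stream's
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, globalenv())
  })
  assign(".Random.seed", stream, globalenv())
  expr
}

#' Generate a population of spike trains with synchrony groups
#'
#' Draws one train per unit from its ISI specification, except that units
#' listed together in a synchrony group share one train verbatim (100%
#' synchrony: identical spike times). Synchronizing k equal-amplitude
#' inputs is therefore exactly equivalent to a single input of k-fold
#' amplitude. Each unit (or group, via its first member) owns an
#' independent RNG substream derived from `seed`, so regrouping or adding
#' units never perturbs the other units' trains.
#'
#' @param specs named list of [isi_lognormal()]-style specifications, one
#'   per unit; names are the unit ids. A `NULL` entry marks a silent unit
#'   (empty train).
#' @param groups list of character vectors of unit ids; groups must be
#'   disjoint and all members of a group must share one target rate. A
#'   singleton group is equivalent to an unsynchronized unit.
#' @param duration train duration in seconds.
#' @param seed master integer seed.
#' @return Named list of [spike_train()] objects, one per unit.
#' @examples
#' specs <- setNames(rep(list(isi_lognormal(80)), 4), paste0("u", 1:4))
#' tr <- assign_synchrony(specs, groups = list(c("u1", "u2")),
#'                        duration = 1, seed = 7)
#' identical(tr$u1$times, tr$u2$times)   # TRUE
#' @export
assign_synchrony <- function(specs, groups = list(), duration, seed) {
  ids <- names(specs)
  if (is.null(ids) || anyDuplicated(ids))
    stopf("specs must be a named list with unique unit ids")
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members))
    stopf("synchrony groups must be disjoint (unit(s) %s repeated)",
          paste(unique(members[duplicated(members)]), collapse = ", "))
  if (length(members) && !all(members %in% ids))
    stopf("synchrony group member(s) %s not found among units",
          paste(setdiff(members, ids), collapse = ", "))
  for (g in groups) {
    rates <- vapply(specs[g], function(s) {
      if (is.null(s)) stopf("silent units cannot join a synchrony group")
      s$rate
    }, numeric(1))
    if (length(unique(rates)) > 1L)
      stopf("all members of a synchrony group must share one rate")
  }
  streams <- rng_substreams(seed, length(specs))
  trains <- vector("list", length(specs))
  names(trains) <- ids
  leader_of <- setNames(ids, ids)
  for (g in groups) {
    lead <- g[which.min(match(g, ids))]
    leader_of[g] <- lead
  }
  for (lead in unique(leader_of)) {
    idx <- match(lead, ids)
    tr <- if (is.null(specs[[lead]])) {
      spike_train(numeric(0), duration, lead)  # silent unit
    } else {
      with_rng_stream(streams[[idx]],
                      generate_train(specs[[lead]], duration, lead))
    }
    for (m in ids[leader_of == lead]) {
      tm <- tr
      tm$unit_id <- m
      trains[[m]] <- tm
    }
  }
  trains
}
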