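## Monte Carlo models of mtDNA deletion formation.
##
## Six generation schemata share a common skeleton: a deletion start
## point is drawn from a model-specific distribution, an end point from a
## second distribution, and candidates are filtered: hard rejection of
## impossible lengths and of deletions impinging upon the origin they
## proceed from (replication-anchored models), plus soft selection --
## candidates covering a selected-against replication origin survive with
## probability `sel`.  Models:
##
##   1 replication-independent, length-independent: both termini uniform;
##     selection against the 7S-3' terminus only.
##   2 replication-independent, length-dependent: uniform start, normal
##     length; selection against 7S-3' only.
##   3 unidirectional H-strand synthesis from 7S-3' (continuous):
##     exponential start offset from 7S-3', normal length; single
##     direction; selects against oriL (7S-3' impingement is hard).
##   4 as model 3 without oriL selection.
##   5 bidirectional (strand-coupled) from 7S-3': both directions
##     anchored at 7S-3'; selects against oriL.
##   6 asynchronous strand displacement: clockwise deletions anchored at
##     7S-3', counterclockwise at oriL; exponential offsets, normal
##     lengths; each direction selects against the opposite origin (its
##     own is hard).
##
## Clockwise and counterclockwise directions share parameters; no model
## has more than five adjustable parameters (scale, sel, mu, sigma,
## shape).

MODEL_DIRECTIONS <- list(`1` = c("cw", "ccw"), `2` = c("cw", "ccw"),
                         `3` = "cw", `4` = "cw",
                         `5` = c("cw", "ccw"), `6` = c("cw", "ccw"))

#' Configuration for a replication/deletion Monte Carlo model
#'
#' @param model_id Integer 1..6 (see the model table in the package
#'   vignette).
#' @param params Named list of adjustable parameters: `scale` (linear
#'   scaling of the output histogram), `sel` (selection coefficient in
#'   `[0, 1]`), `mu`, `sigma` (mean/SD of the normal deletion-length
#'   distribution, bp; models 2-6), `shape` (mean of the exponential
#'   start-offset distribution, bp; models 3-6).
#' @param n_per_direction Accepted deletions per applicable direction
#'   (default 240,000; models 3 and 4 run a single direction).
#' @param sevenS3,oriL Origin positions (bp).
#' @param L Reference length (bp).
#' @param seed RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(model_id, params = list(), n_per_direction = 240000L,
                       sevenS3 = 16070L, oriL = 5780L, L = 16571L,
                       seed = 1L) {
  model_id <- as.integer(model_id)
  stopifnot(model_id %in% 1:6)
  defaults <- list(scale = 1, sel = 0.3, mu = 9000, sigma = 3000,
                   shape = 800)
  p <- utils::modifyList(defaults, params)
  if (p$sel < 0 || p$sel > 1) stop("sel must lie in [0, 1]")
  used <- model_param_names(model_id)
  structure(list(model_id = model_id, params = p[used],
                 n_per_direction = as.integer(n_per_direction),
                 sevenS3 = as.integer(sevenS3), oriL = as.integer(oriL),
                 L = as.integer(L), seed = as.integer(seed)),
            class = "sim_config")
}

model_param_names <- function(model_id) {
  switch(model_id,
         c("scale", "sel"),                      # 1
         c("scale", "sel", "mu", "sigma"),       # 2
         c("scale", "sel", "mu", "sigma", "shape"),
         c("scale", "sel", "mu", "sigma", "shape"),
         c("scale", "sel", "mu", "sigma", "shape"),
         c("scale", "sel", "mu", "sigma", "shape"))
}

circ <- function(p, L) ((as.integer(p) - 1L) %% L) + 1L

## circular span length from ls5 forward to hs5
circ_len <- function(ls5, hs5, L) ((hs5 - ls5) %% L) + 1L

#' Draw candidate deletions for one direction of a model
#'
#' Vectorized: draws `n` candidates from the model's start/end
#' distributions without filtering.
#'
#' @param config A [sim_config()].
#' @param direction `"cw"` (anchored at 7S-3' where applicable) or
#'   `"ccw"`.
#' @param n Number of candidates.
#' @return data.frame `ls5`, `hs5`, `len` (may be invalid; see
#'   [filter_candidates()]), positions in `[1, L]`, `len` unbounded.
#' @export
draw_deletion <- function(config, direction = c("cw", "ccw"), n) {
  direction <- match.arg(direction)
  p <- config$params
  L <- config$L
  m <- config$model_id
  if (m == 1L) {
    ls5 <- sample.int(L, n, replace = TRUE)
    hs5 <- sample.int(L, n, replace = TRUE)
    return(data.frame(ls5 = ls5, hs5 = hs5, len = circ_len(ls5, hs5, L)))
  }
  len <- as.integer(round(rnorm(n, p$mu, p$sigma)))
  if (m == 2L) {
    start <- sample.int(L, n, replace = TRUE)
    if (direction == "cw") {  # deletion extends toward lower coordinates
      hs5 <- start
      ls5 <- circ(start - len + 1L, L)
    } else {
      ls5 <- start
      hs5 <- circ(start + len - 1L, L)
    }
    return(data.frame(ls5 = ls5, hs5 = hs5, len = len))
  }
  off <- as.integer(floor(rexp(n, rate = 1 / p$shape)))
  anchor_7s <- m %in% 3:5 || (m == 6L && direction == "cw")
  if (anchor_7s && direction == "cw") {
    hs5 <- circ(config$sevenS3 - 1L - off, L)
    ls5 <- circ(hs5 - len + 1L, L)
  } else if (anchor_7s) {                 # model 5 ccw, anchored at 7S-3'
    ls5 <- circ(config$sevenS3 + 1L + off, L)
    hs5 <- circ(ls5 + len - 1L, L)
  } else {                                # model 6 ccw, anchored at oriL
    ls5 <- circ(config$oriL + 1L + off, L)
    hs5 <- circ(ls5 + len - 1L, L)
  }
  data.frame(ls5 = ls5, hs5 = hs5, len = len)
}

own_origin <- function(config, direction) {
  m <- config$model_id
  if (m %in% 3:5) return(config$sevenS3)
  if (m == 6L) return(if (direction == "cw") config$sevenS3 else config$oriL)
  NA_integer_
}

soft_origins <- function(config, direction) {
  m <- config$model_id
  own <- own_origin(config, direction)
  sel_set <- switch(m,
                    config$sevenS3,                    # 1
                    config$sevenS3,                    # 2
                    c(config$sevenS3, config$oriL),    # 3
                    config$sevenS3,                    # 4
                    c(config$sevenS3, config$oriL),    # 5
                    c(config$sevenS3, config$oriL))    # 6
  setdiff(sel_set, own)
}

covers_circ <- function(ls5, len, p, L) {
  # deleted arc starts at ls5 and runs len bases forward (circularly)
  ((p - ls5) %% L) < len
}

#' Filter candidate deletions
#'
#' Applies, in order: hard rejection of `len < 1` and `len > L`; hard
#' rejection of candidates impinging on their own anchoring origin
#' (models 3-6); soft selection against the model's selected-against
#' origins -- a uniform draw per covering candidate, rejected when it
#' exceeds `sel`.
#'
#' @param cand Candidates from [draw_deletion()].
#' @param config A [sim_config()].
#' @param direction Direction the candidates were drawn for.
#' @return List: `accepted` (data.frame `ls5`, `hs5`, `len`),
#'   `rejections` (named counts: `length_lt_1`, `exceeds_reference`,
#'   `impinges_own_origin`, `origin_selection`).
#' @export
filter_candidates <- function(cand, config, direction = "cw") {
  L <- config$L
  rej <- c(length_lt_1 = 0L, exceeds_reference = 0L,
           impinges_own_origin = 0L, origin_selection = 0L)
  ok <- cand$len >= 1L
  rej["length_lt_1"] <- sum(!ok)
  big <- ok & cand$len > L
  rej["exceeds_reference"] <- sum(big)
  ok <- ok & !big
  own <- own_origin(config, direction)
  if (!is.na(own)) {
    imp <- ok & covers_circ(cand$ls5, cand$len, own, L)
    rej["impinges_own_origin"] <- sum(imp)
    ok <- ok & !imp
  }
  for (p in soft_origins(config, direction)) {
    cov <- ok & covers_circ(cand$ls5, cand$len, p, L)
    u <- runif(length(cand$ls5))
    drop <- cov & u > config$params$sel
    rej["origin_selection"] <- rej["origin_selection"] + sum(drop)
    ok <- ok & !drop
  }
  list(accepted = cand[ok, , drop = FALSE], rejections = rej)
}

#' Run a replication/deletion Monte Carlo simulation
#'
#' Draws and filters candidates until `n_per_direction` deletions are
#' accepted in each applicable direction, then bins accepted termini into
#' a terminus histogram (same binning as [terminus_histogram()]).
#' Reproducible under the config seed.
#'
#' @param config A [sim_config()].
#' @param bin_bp Histogram bin width (default 250 bp).
#' @return A `sim_result`: list with `deletions` (data.frame `ls5`,
#'   `hs5`, `len`, `direction`), `histogram` (a `terminus_histogram`
#'   scaled by `params$scale`), `rejections`, `attempts`, `config`.
#' @export
simulate_deletions <- function(config, bin_bp = 250L) {
  set.seed(config$seed)
  all_acc <- NULL
  rej_total <- c(length_lt_1 = 0L, exceeds_reference = 0L,
                 impinges_own_origin = 0L, origin_selection = 0L)
  attempts <- 0L
  accepted_raw <- 0L
  for (dir in MODEL_DIRECTIONS[[as.character(config$model_id)]]) {
    acc <- NULL
    n_acc <- 0L
    acc_rate <- 0.5            # running acceptance estimate for chunk sizing
    while (n_acc < config$n_per_direction) {
      need <- config$n_per_direction - n_acc
      n_draw <- as.integer(min(5e6, max(1000L, need / acc_rate * 1.2)))
      cand <- draw_deletion(config, dir, n_draw)
      attempts <- attempts + n_draw
      fl <- filter_candidates(cand, config, dir)
      rej_total <- rej_total + fl$rejections
      acc <- rbind(acc, fl$accepted)
      n_acc <- n_acc + nrow(fl$accepted)
      accepted_raw <- accepted_raw + nrow(fl$accepted)
      acc_rate <- max((nrow(fl$accepted) + 1) / (n_draw + 1), 1e-4)
      if (attempts > 1e5 && (accepted_raw + 1) / attempts < 1e-4)
        stop("acceptance rate below 1e-4: pathological parameters")
    }
    acc <- acc[seq_len(config$n_per_direction), , drop = FALSE]
    acc$direction <- dir
    all_acc <- rbind(all_acc, acc)
  }
  # chunks may overshoot n_per_direction; the surplus is trimmed from the
  # output but retained in `accepted_raw` so that conservation
  # (attempts = accepted_raw + rejections) is exact
  th <- terminus_histogram_spans(all_acc$ls5, all_acc$hs5,
                                 rep(config$params$scale, nrow(all_acc)),
                                 config$L, bin_bp)
  structure(list(deletions = all_acc, histogram = th,
                 rejections = rej_total, attempts = attempts,
                 accepted_raw = accepted_raw, config = config),
            class = "sim_result")
}

## ---- fitting -------------------------------------------------------------

log_domain_metrics <- function(obs, sim_counts, eps) {
  # profile out the linear scale by a 1-d search in log space
  f <- function(ls) {
    s <- exp(ls)
    sum((log(s * sim_counts + eps) - log(obs + eps))^2)
  }
  tot <- sum(obs)
  init <- log(max(tot, eps) / max(sum(sim_counts), 1))
  op <- optimize(f, interval = init + c(-8, 8))
  lobs <- log(obs + eps)
  r2 <- 1 - op$objective / sum((lobs - mean(lobs))^2)
  list(loss = op$objective, scale = exp(op$minimum), r2 = r2)
}

#' Fit a Monte Carlo model to an observed terminus histogram
#'
#' Minimizes the log-domain least-squares difference between the
#' simulated and observed LS5'/HS5' terminus densities over the model's
#' adjustable parameters, using derivative-free simplex search with three
#' deterministic restarts, parameter bounds enforced by clipping, and
#' common random numbers (a fixed per-evaluation seed) so the objective
#' surface is smooth.  The pseudo-count added before taking logs is half
#' the smallest nonzero observed bin.
#'
#' @param observed A `terminus_histogram`.
#' @param model_id Model 1..6.
#' @param init Named list of starting parameter values (defaults from
#'   [sim_config()]).
#' @param bounds Named list of `c(lo, hi)` bounds per parameter.
#' @param seed Seed for the common-random-number stream.
#' @param n_per_direction Accepted deletions per direction per objective
#'   evaluation; a vector gives a refinement schedule (coarse search at
#'   the first value, then chained refinement rounds at each later value,
#'   whose larger simulations lower the Monte Carlo noise floor of the
#'   objective).  Final metrics use the last value.
#' @param sevenS3,oriL,L Geometry passed to [sim_config()].
#' @param maxit Simplex iterations per restart.
#' @return List: `params` (best-fit, including the profiled `scale`),
#'   `r2` (log-domain R^2 against the observed histogram), `loss`,
#'   `model_id`, `convergence`.
#' @export
fit_model <- function(observed, model_id, init = list(), bounds = list(),
                      seed = 1L, n_per_direction = 20000L,
                      sevenS3 = 16070L, oriL = 5780L, L = 16571L,
                      maxit = 200L) {
  obs <- c(observed$ls5_freq, observed$hs5_freq)
  if (sum(obs) <= 0) stop("observed histogram is empty")
  eps <- min(obs[obs > 0]) / 2
  free <- setdiff(model_param_names(model_id), "scale")
  defaults <- list(sel = 0.5, mu = 8000, sigma = 2500, shape = 1000)
  start <- unlist(utils::modifyList(defaults[free], init[names(init) %in% free]))
  default_bounds <- list(sel = c(0, 1), mu = c(100, L), sigma = c(10, L / 2),
                         shape = c(10, L / 2))
  bnd <- utils::modifyList(default_bounds[free],
                           bounds[names(bounds) %in% free])
  lo <- vapply(bnd, `[`, 0.0, 1L)
  hi <- vapply(bnd, `[`, 0.0, 2L)
  # search in bound-normalized coordinates (all parameters in [0, 1],
  # clipped), so the simplex treats sel and mu on an equal footing
  to_unit <- function(v) (v - lo) / (hi - lo)
  from_unit <- function(u) lo + pmin(pmax(u, 0), 1) * (hi - lo)
  objective_at_n <- function(n, eval_seed = seed) function(u) {
    v <- setNames(from_unit(u), free)
    cfg <- sim_config(model_id, params = as.list(v),
                      n_per_direction = n,
                      sevenS3 = sevenS3, oriL = oriL, L = L,
                      seed = eval_seed)
    sim <- try(simulate_deletions(cfg, bin_bp = observed$bin_size),
               silent = TRUE)
    if (inherits(sim, "try-error")) return(1e12)
    simv <- c(sim$histogram$ls5_freq, sim$histogram$hs5_freq)
    log_domain_metrics(obs, simv, eps)$loss
  }
  # schedule: coarse rounds at n_per_direction[1] from two starts, then a
  # refinement round at each further n, chained from the incumbent best.
  # Refinement at larger n lowers the Monte Carlo noise floor of the
  # objective, which otherwise manufactures false local minima along the
  # sel/mu/shape ridge.
  n_sched <- as.integer(n_per_direction)
  best <- NULL
  set.seed(seed)
  u0 <- to_unit(pmin(pmax(start, lo), hi))
  conv <- 1L
  if (length(free) == 1L) {
    o <- optimize(objective_at_n(n_sched[length(n_sched)]), c(0, 1))
    best <- list(par = o$minimum, value = o$objective)
    conv <- 0L
  } else {
    # stage 0: Latin-hypercube pre-screen picks basins for the simplex;
    # simplex search alone reliably strands on the curved sel/mu/shape
    # ridge these objectives exhibit
    d <- length(free)
    n0 <- 16L * d
    grid <- vapply(seq_len(d), function(j)
      (sample.int(n0) - runif(n0)) / n0, numeric(n0))
    grid <- rbind(grid, u0)
    f0 <- objective_at_n(n_sched[1])
    v0 <- apply(grid, 1L, f0)
    top <- order(v0)[1:2]
    starts <- list(grid[top[1L], ], grid[top[2L], ])
    rounds <- c(n_sched[1], n_sched[1],
                rep(n_sched[-1], each = if (length(n_sched) > 1) 2 else 0))
    if (length(rounds) == 2L) rounds <- c(rounds, n_sched[1])
    for (r in seq_along(rounds)) {
      s0 <- if (r <= length(starts)) starts[[r]] else best$par
      # refinement rounds use distinct common-random-number streams, so a
      # noise artifact of one stream is not revisited by the next
      es <- if (r <= 2L) seed else seed + r
      op <- optim(pmin(pmax(s0, 0), 1), objective_at_n(rounds[r], es),
                  method = "Nelder-Mead",
                  control = list(maxit = maxit, reltol = 1e-7))
      if (r > 2L || is.null(best) || op$value < best$value) {
        # later rounds supersede: their objective is less noisy
        best <- op
        conv <- op$convergence
      }
    }
  }
  par <- setNames(from_unit(best$par), free)
  n_final <- n_sched[length(n_sched)]
  cfg <- sim_config(model_id, params = as.list(par),
                    n_per_direction = n_final,
                    sevenS3 = sevenS3, oriL = oriL, L = L, seed = seed)
  sim <- simulate_deletions(cfg, bin_bp = observed$bin_size)
  met <- log_domain_metrics(obs, c(sim$histogram$ls5_freq,
                                   sim$histogram$hs5_freq), eps)
  if (conv != 0L)
    warning("model ", model_id,
            " fit did not converge within budget; best-so-far reported")
  list(params = c(as.list(par), scale = met$scale), r2 = met$r2,
       loss = met$loss, model_id = model_id, convergence = conv)
}

#' Fit and rank several Monte Carlo models against an observed histogram
#'
#' @inheritParams fit_model
#' @param model_ids Models to fit (default 1:6).
#' @return data.frame ranked by decreasing log-domain R^2, with one row
#'   per model (`model_id`, `r2`, `loss`, and fitted parameters).
#' @export
compare_models <- function(observed, model_ids = 1:6, seed = 1L,
                           n_per_direction = 20000L, sevenS3 = 16070L,
                           oriL = 5780L, L = 16571L, maxit = 60L) {
  fits <- lapply(model_ids, function(m)
    fit_model(observed, m, seed = seed, n_per_direction = n_per_direction,
              sevenS3 = sevenS3, oriL = oriL, L = L, maxit = maxit))
  df <- data.frame(model_id = vapply(fits, `[[`, 0L, "model_id"),
                   r2 = vapply(fits, `[[`, 0.0, "r2"),
                   loss = vapply(fits, `[[`, 0.0, "loss"),
                   sel = vapply(fits, function(f)
                     f$params$sel %||% NA_real_, 0.0),
                   mu = vapply(fits, function(f)
                     f$params$mu %||% NA_real_, 0.0),
                   sigma = vapply(fits, function(f)
                     f$params$sigma %||% NA_real_, 0.0),
                   shape = vapply(fits, function(f)
                     f$params$shape %||% NA_real_, 0.0))
  df <- df[order(-df$r2), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "fits") <- fits
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
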