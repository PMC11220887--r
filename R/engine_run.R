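#' Engine configuration
#'
#' Collects the tunable parameters of the modified phase-retrieval
#' iteration with their working defaults: relaxation beta = 0.82,
#' perturbed low-density fraction = 13%, weak fraction automatic over
#' 20-50%, strong-set size by [n_tf_rule()], tangent refinement every 20
#' iterations after cycle 100, 500 iterations per trial, 400 trials.
#'
#' @param beta RAAR relaxation coefficient, in (0, 1)
#' @param perturb_fraction fraction of grid points in the low-density
#'   branch, in (0, 1)
#' @param w_best weak-reflection fraction, numeric or "auto" (trials
#'   spread over 0.20, 0.30, 0.40, 0.50)
#' @param n_tf strong-set size; NULL = automatic rule
#' @param tf_start first iteration eligible for tangent refinement
#' @param tf_stride apply tangent refinement every this many iterations
#' @param n_iter Fourier iterations per trial (500 or 750 typical)
#' @param n_trials number of random starts
#' @param algorithm one of "cf", "raar", "raar_pihalf", "raar_pihalf_tf"
#' @param seed master seed; trial i runs with seed + i
#' @param delta_mode "perturbed" (13% of points perturbed) or "pass"
#' @param pihalf_sign +1 or -1, direction of the 90 degree shift
#' @param weak_keep_calc keep calculated moduli on weak reflections
#'   instead of replacing by observed (variant switch)
#' @param weak_mode "fixed" (weak set ranked once by E_obs) or "dynamic"
#'   (re-ranked every cycle by the calculated moduli)
#' @param grid_factor grid oversampling (spacing <= d_min/grid_factor;
#'   3 avoids aliasing ghosts from the positivity step)
#' @return list of class `engine_config`
#' @export
engine_config <- function(beta = 0.82, perturb_fraction = 0.13,
                          w_best = "auto", n_tf = NULL, tf_start = 100,
                          tf_stride = 20, n_iter = 500, n_trials = 400,
                          algorithm = c("raar_pihalf_tf", "raar_pihalf",
                                        "raar", "cf"),
                          seed = 1, delta_mode = c("perturbed", "pass"),
                          pihalf_sign = 1, weak_keep_calc = FALSE,
                          weak_mode = c("fixed", "dynamic"),
                          grid_factor = 3) {
  algorithm <- match.arg(algorithm)
  delta_mode <- match.arg(delta_mode)
  weak_mode <- match.arg(weak_mode)
  stopifnot(beta > 0, beta < 1, perturb_fraction > 0, perturb_fraction < 1,
            n_iter >= 1, n_trials >= 1, tf_stride >= 1)
  if (!identical(w_best, "auto"))
    stopifnot(is.numeric(w_best), w_best >= 0, w_best <= 1)
  cfg <- list(beta = beta, perturb_fraction = perturb_fraction,
              w_best = w_best, n_tf = n_tf, tf_start = tf_start,
              tf_stride = tf_stride, n_iter = n_iter, n_trials = n_trials,
              algorithm = algorithm, seed = seed, delta_mode = delta_mode,
              pihalf_sign = pihalf_sign, weak_keep_calc = weak_keep_calc,
              weak_mode = weak_mode, grid_factor = grid_factor)
  class(cfg) <- "engine_config"
  cfg
}

.alg_code <- c(cf = 0L, raar = 1L, raar_pihalf = 2L, raar_pihalf_tf = 3L)

# weak/strong index sets for a given weak fraction
.weak_strong <- function(problem, w_best, n_tf) {
  obs_i <- which(problem$obs)
  weak <- logical(nrow(problem$hkl))
  n_weak <- floor(w_best * length(obs_i))
  if (n_weak > 0)
    weak[obs_i[order(problem$E_obs[obs_i])][seq_len(n_weak)]] <- TRUE
  strong_i <- obs_i[order(-problem$E_obs[obs_i])][seq_len(min(n_tf,
                                                              length(obs_i)))]
  list(weak = weak, strong = strong_i)
}

#' Detect convergence in a CC trace
#'
#' Operationalizes the "abrupt CC increase" signature: converged when the
#' CC gains more than `jump` over some `window`-iteration span and then
#' plateaus near its maximum.
#'
#' @param cc numeric CC trace
#' @param window span in iterations (default 50)
#' @param jump minimum gain over the window (default 0.05)
#' @return list(converged, jump_iter) where jump_iter is the first
#'   iteration completing such a gain (NA if none)
#' @export
detect_convergence <- function(cc, window = 50, jump = 0.05) {
  n <- length(cc)
  if (n < 2) return(list(converged = FALSE, jump_iter = NA_integer_))
  lag <- pmax(seq_len(n) - window, 1)
  gain <- cc - cc[lag]
  hit <- which(gain[-1] > jump) + 1L
  if (!length(hit)) return(list(converged = FALSE, jump_iter = NA_integer_))
  plateau <- mean(tail(cc, min(25, n))) >= max(cc) - 0.05
  list(converged = plateau, jump_iter = as.integer(hit[1]))
}

#' Run one phase-retrieval trial
#'
#' Executes `n_iter` dual-space cycles from a random (or supplied) phase
#' start: synthesis, Laue reduction, moduli replacement, optional pi-half
#' perturbation and scheduled tangent refinement, symmetry expansion,
#' synthesis, and the algorithm's real-space update, recording the Pearson
#' CC between observed and calculated amplitudes at every iteration.
#'
#' @param problem an [build_problem()] result
#' @param config an [engine_config()]
#' @param seed trial seed (defaults to config$seed)
#' @param w_best weak fraction for this trial (numeric; defaults from
#'   config, 0.3 when "auto")
#' @param phases_init optional starting phases (radians, one per unique
#'   reflection) replacing the random start
#' @param return_density return the final constrained map
#' @return list of class `trial_result`: cc_trace, best_cc, final_cc,
#'   converged, jump_iter, phases, e_calc, density (optional), seed,
#'   w_best, ok, plus reality diagnostics max_imag_ratio / max_abs_mean
#' @export
run_trial <- function(problem, config = engine_config(), seed = config$seed,
                      w_best = NULL, phases_init = NULL,
                      return_density = FALSE) {
  if (is.null(w_best))
    w_best <- if (identical(config$w_best, "auto")) 0.3 else config$w_best
  n_tf <- if (is.null(config$n_tf)) n_tf_rule(problem$n_obs) else config$n_tf
  ws <- .weak_strong(problem, w_best, n_tf)
  res <- run_trial_cpp(
    as.integer(problem$dims), problem$member_off, problem$member_idx,
    problem$member_ph, problem$member_conj, problem$member_wt,
    problem$E_obs, problem$obs, ws$weak, as.integer(ws$strong - 1L),
    .alg_code[[config$algorithm]], config$beta, config$perturb_fraction,
    if (config$delta_mode == "pass") 1L else 0L,
    as.integer(config$n_iter), as.integer(config$tf_start),
    as.integer(config$tf_stride), config$pihalf_sign,
    isTRUE(config$weak_keep_calc),
    identical(config$weak_mode, "dynamic"),
    as.integer(floor(w_best * problem$n_obs)), as.integer(seed),
    if (is.null(phases_init)) numeric(0) else as.numeric(phases_init),
    return_density, as.integer(problem$tf_dims), problem$tf_member_idx,
    problem$tf_member_wt)
  conv <- detect_convergence(res$cc_trace)
  out <- list(cc_trace = res$cc_trace,
              best_cc = max(tail(res$cc_trace, min(50, config$n_iter))),
              final_cc = res$cc_trace[length(res$cc_trace)],
              converged = conv$converged, jump_iter = conv$jump_iter,
              phases = res$phases, e_calc = res$e_calc,
              max_imag_ratio = res$max_imag_ratio,
              max_abs_mean = res$max_abs_mean,
              seed = seed, w_best = w_best, ok = res$ok)
  if (return_density) out$density <- res$density
  class(out) <- "trial_result"
  out
}

#' Run a multi-trial substructure search
#'
#' Runs `config$n_trials` trials with seeds `config$seed + i`.  When
#' `w_best` is "auto", trials are allocated evenly (round-robin) over the
#' grid 0.20 / 0.30 / 0.40 / 0.50.  The winner is the trial with the
#' highest CC (over the trace tail) among those passing a map-skewness
#' plausibility screen: trials whose density skewness falls below
#' `skew_screen` times the ensemble maximum are set aside, because rare
#' high-CC solutions with diagnostically flat (low-skew) maps are
#' enantiomorph-superposition artifacts rather than substructures.  Set
#' `skew_screen = 0` to rank purely by CC.
#'
#' @param problem an [build_problem()] result
#' @param config an [engine_config()]
#' @param skew_screen fraction of the maximum trial skewness below which a
#'   trial is excluded from winner selection (default 0.6)
#' @return list of class `multi_result`: best (a `trial_result` with
#'   density), summary (data frame with per-trial CC, convergence and
#'   skewness), w_grid
#' @export
run_multi <- function(problem, config = engine_config(), skew_screen = 0.6) {
  grid <- if (identical(config$w_best, "auto")) c(0.2, 0.3, 0.4, 0.5)
          else config$w_best
  n <- config$n_trials
  rows <- vector("list", n)
  skews <- numeric(n)
  trs <- vector("list", n)
  for (i in seq_len(n)) {
    wb <- grid[(i - 1) %% length(grid) + 1]
    tr <- run_trial(problem, config, seed = config$seed + i, w_best = wb,
                    return_density = TRUE)
    v <- as.vector(tr$density)
    z <- v - mean(v)
    skews[i] <- mean(z^3) / (sqrt(mean(z^2))^3)
    rows[[i]] <- data.frame(trial = i, seed = tr$seed, w_best = wb,
                            final_cc = tr$final_cc, best_cc = tr$best_cc,
                            converged = tr$converged,
                            jump_iter = if (is.na(tr$jump_iter)) NA_integer_
                                        else tr$jump_iter,
                            skew = skews[i], ok = tr$ok)
    trs[[i]] <- tr
  }
  summary <- do.call(rbind, rows)
  if (!any(summary$ok)) stop("all trials failed (non-finite density)")
  eligible <- summary$ok
  if (skew_screen > 0 && max(skews[summary$ok]) > 0)
    eligible <- eligible & skews >= skew_screen * max(skews[summary$ok])
  if (!any(eligible)) eligible <- summary$ok
  best_i <- which(eligible)[which.max(summary$best_cc[eligible])]
  out <- list(best = trs[[best_i]], summary = summary,
              w_grid = grid, n_converged = sum(summary$converged))
  class(out) <- "multi_result"
  out
}

#' @export
print.multi_result <- function(x, ...) {
  cat(sprintf("%d trials, %d converged; best CC %.3f (seed %d, w_best %.2f)\n",
              nrow(x$summary), x$n_converged, x$best$best_cc, x$best$seed,
              x$best$w_best))
  invisible(x)
}
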