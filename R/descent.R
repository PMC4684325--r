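#' Control parameters of the coordinate-descent fitting schedule
#'
#' The nested fitting algorithm sweeps an outer stop criterion `epsilon` from
#' `eps0` downward by the factor `eps_decay` per round (i.e. a 30% reduction
#' with the default 0.7), to a floor of `eps_floor_nonl_off` while the output
#' nonlinearity is removed and `eps_floor_nonl_on` once it is restored.
#' Within a module visit, probe steps of size `delta` grow by `delta_up` on
#' success and shrink by `delta_down` on failure, starting at `delta0` and
#' bounded below by `delta_floor`; at most `max_steps_per_visit` accepted
#' steps are taken per visit (per parameter for greedy descent).
#'
#' @param eps0 initial stop criterion (cost units; the shrunken NMSE lies in
#'   \[0, 1\]).
#' @param eps_decay multiplicative criterion reduction per round.
#' @param eps_floor_nonl_off,eps_floor_nonl_on epsilon floors for the phases
#'   without / with the output nonlinearity.
#' @param delta0 initial probe step size.
#' @param delta_up,delta_down step growth / shrink factors.
#' @param delta_floor smallest allowed step.
#' @param max_steps_per_visit accepted-step cap per visit.
#' @param jackknife_folds folds of the shrinkage jackknife.
#' @param max_passes cap on module passes per epsilon round.
#' @param seed integer seed recorded with the fit (the descent itself is
#'   deterministic).
#' @return List of class `"strf_control"`.
#' @export
strf_control <- function(eps0 = 1e-3, eps_decay = 0.7,
                         eps_floor_nonl_off = 1e-4,
                         eps_floor_nonl_on = 1e-6,
                         delta0 = 1, delta_up = 1.1, delta_down = 0.5,
                         delta_floor = 1e-6, max_steps_per_visit = 10,
                         jackknife_folds = 10, max_passes = 10, seed = 1L) {
  if (eps_decay <= 0 || eps_decay >= 1) stop("need 0 < eps_decay < 1")
  if (delta_floor <= 0) stop("delta_floor must be > 0")
  structure(list(eps0 = eps0, eps_decay = eps_decay,
                 eps_floor_nonl_off = eps_floor_nonl_off,
                 eps_floor_nonl_on = eps_floor_nonl_on,
                 delta0 = delta0, delta_up = delta_up,
                 delta_down = delta_down, delta_floor = delta_floor,
                 max_steps_per_visit = max_steps_per_visit,
                 jackknife_folds = jackknife_folds,
                 max_passes = max_passes, seed = as.integer(seed)),
            class = "strf_control")
}

#' Non-greedy coordinate descent (one module visit)
#'
#' Probes every parameter at +/- a shared step `delta` and accepts only the
#' single step that decreases the cost the most (ties broken toward the
#' lowest parameter index). On success `delta` grows by `delta_up`; when no
#' probe improves, `delta` shrinks by `delta_down`. The visit ends when the
#' accepted improvement falls to `eps` or below, when `delta` reaches
#' `delta_floor`, or after `max_steps_per_visit` accepted steps.
#'
#' @param par numeric parameter vector.
#' @param fn cost function of `par`; must return a finite scalar (non-finite
#'   values are treated as non-improving).
#' @param control an [strf_control()].
#' @param eps stop criterion for this visit.
#' @param sweep_fn optional specialized probe sweep `function(par, delta)`
#'   returning `list(j, sign, cost)` for the best probe (used internally for
#'   modules with a fast linear probe path).
#' @param accept_fn optional callback `function(j, sign, delta)` invoked when
#'   a step is accepted (lets `sweep_fn` maintain cached state).
#' @return List with `par`, `cost`, accepted `steps`, and total `improvement`.
#' @export
descent_nongreedy <- function(par, fn, control = strf_control(),
                              eps = control$eps0,
                              sweep_fn = NULL, accept_fn = NULL) {
  cur <- fn(par)
  if (!is.finite(cur)) stop("non-finite cost at initial parameters")
  delta <- control$delta0
  steps <- 0L
  total <- 0
  repeat {
    if (is.null(sweep_fn)) {
      best_cost <- cur
      best_j <- NA_integer_
      best_sign <- 0
      for (j in seq_along(par)) {
        for (sgn in c(1, -1)) {
          th <- par
          th[j] <- th[j] + sgn * delta
          cc <- fn(th)
          if (is.finite(cc) && cc < best_cost) {
            best_cost <- cc
            best_j <- j
            best_sign <- sgn
          }
        }
      }
      sw <- list(j = best_j, sign = best_sign, cost = best_cost)
    } else {
      sw <- sweep_fn(par, delta)
    }
    if (!is.na(sw$j) && sw$j > 0 && is.finite(sw$cost) && sw$cost < cur) {
      par[sw$j] <- par[sw$j] + sw$sign * delta
      if (!is.null(accept_fn)) accept_fn(sw$j, sw$sign, delta)
      impr <- cur - sw$cost
      cur <- sw$cost
      steps <- steps + 1L
      total <- total + impr
      delta <- delta * control$delta_up
      if (impr <= eps || steps >= control$max_steps_per_visit) break
    } else {
      delta <- delta * control$delta_down
      if (delta <= control$delta_floor) break
    }
  }
  list(par = par, cost = cur, steps = steps, improvement = total)
}

#' Greedy coordinate descent (one module visit)
#'
#' Iterates each parameter to its own stop condition before moving to the
#' next: parameter `i` keeps its own step size `delta_i`, takes the better of
#' the +/- probes while one improves, and stops when the improvement falls to
#' `eps`, `delta_i` reaches the floor, or `max_steps_per_visit` accepted
#' steps have been taken for that parameter.
#'
#' @inheritParams descent_nongreedy
#' @return List with `par`, `cost`, total accepted `steps`, and total
#'   `improvement`.
#' @export
descent_greedy <- function(par, fn, control = strf_control(),
                           eps = control$eps0) {
  cur <- fn(par)
  if (!is.finite(cur)) stop("non-finite cost at initial parameters")
  steps <- 0L
  total <- 0
  for (j in seq_along(par)) {
    delta <- control$delta0
    jsteps <- 0L
    repeat {
      best_cost <- cur
      best_sign <- 0
      for (sgn in c(1, -1)) {
        th <- par
        th[j] <- th[j] + sgn * delta
        cc <- fn(th)
        if (is.finite(cc) && cc < best_cost) {
          best_cost <- cc
          best_sign <- sgn
        }
      }
      if (best_sign != 0) {
        par[j] <- par[j] + best_sign * delta
        impr <- cur - best_cost
        cur <- best_cost
        steps <- steps + 1L
        jsteps <- jsteps + 1L
        total <- total + impr
        delta <- delta * control$delta_up
        if (impr <= eps || jsteps >= control$max_steps_per_visit) break
      } else {
        delta <- delta * control$delta_down
        if (delta <= control$delta_floor) break
      }
    }
  }
  list(par = par, cost = cur, steps = steps, improvement = total)
}
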