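#' Advance the tissue for a number of steps
#'
#' The core simulation loop: every step applies one gradient-descent
#' update (with the noise field resampled every `k_noise` steps), at most
#' one topological event (T2 served before T1, shortest/smallest first),
#' and, when differentiation is enabled, at most one lateral-inhibition
#' conversion. Snapshots and order-parameter metrics are recorded at a
#' fixed cadence.
#'
#' @param state a `corti_tissue`.
#' @param params a `corti_params`.
#' @param n_steps number of steps to run.
#' @param record_every snapshot/metric cadence in steps (0 = ends only).
#' @param differentiate allow SC -> HC conversion per the lateral
#'   inhibition rule.
#' @param hc_cap hair-cell cap for differentiation.
#' @param topology enable T1/T2 transitions.
#' @param collect_metrics compute order parameters at each snapshot.
#' @param label protocol label stored on the trajectory.
#' @return a `corti_trajectory`: list with `snapshots` (list of states),
#'   `events` (tibble: step, kind, cells, x, y), `metrics` (tibble, one
#'   row per snapshot), `final` (end state), `params`, `label`.
#' @export
advance <- function(state, params, n_steps, record_every = 250,
                    differentiate = FALSE, hc_cap = Inf, topology = TRUE,
                    collect_metrics = TRUE, label = "run") {
  events <- list()
  snapshots <- list()
  metrics <- list()
  noise <- NULL
  rec <- function(s) {
    snapshots[[length(snapshots) + 1L]] <<- s
    if (collect_metrics)
      metrics[[length(metrics) + 1L]] <<- tissue_metrics(s)
  }
  rec(state)
  for (i in seq_len(n_steps)) {
    if (params$f_noise > 0 &&
        (is.null(noise) || (i - 1L) %% params$k_noise == 0L))
      noise <- noise_force(state, params)
    state <- step_tissue(state, params, noise = noise, on_fail = "freeze")
    if (topology) {
      ts <- topology_events(state, params)
      state <- ts$state
      for (ev in ts$events)
        events[[length(events) + 1L]] <- tibble::tibble(
          step = state$step, kind = ev$kind,
          cells = paste(ev$cells, collapse = ","),
          x = ev$x, y = ev$y)
    }
    if (differentiate) {
      md <- maybe_differentiate(state, hc_cap)
      state <- md$state
      if (!is.null(md$converted)) {
        g <- tissue_geometry(state)
        events[[length(events) + 1L]] <- tibble::tibble(
          step = state$step, kind = "differentiation",
          cells = as.character(md$converted),
          x = g$centroid[md$converted, 1], y = g$centroid[md$converted, 2])
      }
    }
    if (record_every > 0 && i %% record_every == 0L && i < n_steps)
      rec(state)
  }
  rec(state)
  ev <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(step = integer(), kind = character(),
                   cells = character(), x = numeric(), y = numeric())
  new_trajectory(snapshots, ev,
                 if (collect_metrics) dplyr::bind_rows(metrics) else NULL,
                 state, params, label)
}

new_trajectory <- function(snapshots, events, metrics, final, params,
                           label) {
  structure(list(snapshots = snapshots, events = events, metrics = metrics,
                 final = final, params = params, label = label),
            class = "corti_trajectory")
}

#' @export
print.corti_trajectory <- function(x, ...) {
  cat("<corti_trajectory> ", x$label, ": steps ",
      x$snapshots[[1]]$step, "..", x$final$step, ", ",
      length(x$snapshots), " snapshots, ", nrow(x$events), " events\n",
      sep = "")
  if (!is.null(x$metrics)) print(utils::tail(x$metrics, 3))
  invisible(x)
}

#' Tidy a trajectory into its per-snapshot metric series
#' @param x a `corti_trajectory`.
#' @param ... unused.
#' @return the metrics tibble (one row per snapshot).
#' @method tidy corti_trajectory
#' @export
tidy.corti_trajectory <- function(x, ...) {
  if (is.null(x$metrics)) abort_cfg("trajectory was run without metrics")
  x$metrics
}

#' One-row summary of a trajectory
#' @inheritParams tidy.corti_trajectory
#' @return a one-row tibble: protocol label, steps, event counts, and the
#'   end-state order parameters.
#' @method glance corti_trajectory
#' @export
glance.corti_trajectory <- function(x, ...) {
  m <- if (!is.null(x$metrics)) utils::tail(x$metrics, 1) else
    tissue_metrics(x$final)
  tibble::tibble(
    label = x$label,
    steps = x$final$step - x$snapshots[[1]]$step,
    n_t1 = sum(x$events$kind == "T1"),
    n_t2 = sum(x$events$kind == "T2"),
    n_differentiation = sum(x$events$kind == "differentiation"),
    end_n_hc = m$n_hc, end_mean_sc_neighbors = m$mean_sc_neighbors,
    end_mean_psi6_star = m$mean_psi6_star, end_area_ratio = m$area_ratio,
    end_hc_rows = m$hc_rows)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# Merge two trajectories run back to back.
concat_trajectories <- function(a, b, label = b$label) {
  new_trajectory(c(a$snapshots, b$snapshots[-1]),
                 dplyr::bind_rows(a$events, b$events),
                 if (!is.null(a$metrics) && !is.null(b$metrics))
                   dplyr::bind_rows(a$metrics, b$metrics[-1, ]) else NULL,
                 b$final, b$params, label)
}
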