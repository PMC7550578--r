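#' Protocol configuration
#'
#' Stage schedules and bookkeeping options shared by the experiment
#' protocols. Stage lengths are in simulation steps; overrides applied by
#' each protocol are recorded on the returned trajectories.
#'
#' @param steps_stage1,steps_stage2 schedule of the compaction and
#'   refinement stages.
#' @param steps_blebbistatin,steps_ablation,steps_alternative schedules of
#'   the perturbation protocols (the alternative model runs
#'   `steps_alternative` steps from the same initial state; default the
#'   two-stage total).
#' @param record_every snapshot/metric cadence.
#' @param disorder_cycles,relax_steps initializer settings (see
#'   [init_tissue()]).
#' @param collect_metrics compute order parameters at snapshots.
#' @return a `corti_protocol_config` list.
#' @export
protocol_config <- function(steps_stage1 = 12000, steps_stage2 = 8000,
                            steps_blebbistatin = 2000, steps_ablation = 600,
                            steps_alternative = NULL, record_every = 250,
                            disorder_cycles = 10, relax_steps = 100,
                            collect_metrics = TRUE) {
  if (steps_stage1 < 0 || steps_stage2 < 0)
    abort_cfg("stage schedules must be non-negative")
  structure(list(
    steps_stage1 = steps_stage1, steps_stage2 = steps_stage2,
    steps_blebbistatin = steps_blebbistatin,
    steps_ablation = steps_ablation,
    steps_alternative = steps_alternative %||% (steps_stage1 + steps_stage2),
    record_every = record_every, disorder_cycles = disorder_cycles,
    relax_steps = relax_steps, collect_metrics = collect_metrics),
    class = "corti_protocol_config")
}

#' Stage-2 (refinement) parameter overrides
#'
#' Raises the SC:SC junction tension relative to HC:SC, adds high tension
#' on the OHC-facing junctions of the top border (constricting the OHC
#' region), and raises the delamination threshold so that squeezed
#' supporting cells exit the apical plane more readily.
#'
#' @param params stage-1 `corti_params`.
#' @param sc_sc_factor,top_factor tension multipliers (in units of
#'   `gamma_default`).
#' @param A_min_factor delamination-threshold multiplier.
#' @return a `corti_params` for the refinement stage.
#' @export
stage2_params <- function(params, sc_sc_factor = 8, top_factor = 8,
                          A_min_factor = 1.5) {
  params$gamma["SC:SC"] <- sc_sc_factor * params$gamma_default
  params$gamma["HC:top_boundary"] <- top_factor * params$gamma_default
  params$gamma["SC:top_boundary"] <- top_factor * params$gamma_default
  # squeezed supporting cells delaminate more readily during refinement
  params$A_min <- A_min_factor * params$A_min
  validate_params(params)
  params
}

#' Blebbistatin (NMII inhibition) parameter overrides
#'
#' Tension is reduced and equated for all junction types
#' (`gamma = gamma_factor * gamma_default` everywhere), shear and
#' compression are suppressed (`eta = zeta = 0`) and the overall
#' contractility is reduced.
#'
#' @param params stage-2 `corti_params`.
#' @param gamma_factor tension reduction factor.
#' @param Gamma_factor contractility reduction factor.
#' @return a `corti_params` for the inhibition protocol.
#' @export
blebbistatin_params <- function(params, gamma_factor = 0.5,
                                Gamma_factor = 0.5) {
  params$gamma <- c(dummy = 0)[0]     # drop every per-pair override
  params$gamma_default <- gamma_factor * params$gamma_default
  params$eta <- 0
  params$zeta <- 0
  params$Gamma[] <- Gamma_factor * params$Gamma
  validate_params(params)
  params
}

#' Alternative (adhesion-only) model parameters
#'
#' No global forces and no HC/SC difference in compressibility or
#' contractility: `eta = zeta = sigma = 0`, uniform `alpha` and `Gamma`;
#' ordering is driven only by differential junction tension (SC:SC higher
#' than HC:SC).
#'
#' @param params baseline `corti_params`.
#' @param sc_sc_factor SC:SC tension contrast (units of `gamma_default`).
#' @return a `corti_params` for the alternative model.
#' @export
alternative_params <- function(params, sc_sc_factor = 25) {
  # "only the refinement stage": differential tension is the sole driver,
  # with no global forces and no HC/SC mechanical asymmetry. The contrast
  # is set at the high end of its plausible range because weaker
  # contrasts leave the mosaic static: the tension-only mechanism works
  # through junction collapse, so it needs collapses to happen at all.
  params <- stage2_params(params, sc_sc_factor = sc_sc_factor)
  params$eta <- 0
  params$zeta <- 0
  params$sigma <- 0
  # the common baseline is the supporting-cell value, the deformable end
  params$alpha[c("HC", "SC")] <- params$alpha[["SC"]]
  params$Gamma[c("HC", "SC")] <- params$Gamma[["SC"]]
  validate_params(params)
  params
}

#' Stage 1: compaction under global shear and local repulsion
#'
#' Shear and compression act on hair cells, repulsion keeps their
#' centroids apart, differentiation continues under the three-row cap;
#' T1/T2 transitions are interleaved with the relaxation. At completion
#' the top border of the OHC region is labeled, after which statistics
#' are taken.
#'
#' @param state an initialized `corti_tissue` (see [init_tissue()]).
#' @param params a `corti_params`.
#' @param cfg a [protocol_config()].
#' @return a `corti_trajectory`.
#' @export
run_stage1 <- function(state, params = model_params(),
                       cfg = protocol_config()) {
  hc_cap <- attr(state, "hc_cap") %||% Inf
  traj <- advance(state, params, cfg$steps_stage1,
                  record_every = cfg$record_every, differentiate = TRUE,
                  hc_cap = hc_cap, collect_metrics = cfg$collect_metrics,
                  label = "stage1")
  final <- label_top_boundary(traj$final)
  attr(final, "hc_cap") <- hc_cap
  traj$final <- final
  traj$snapshots[[length(traj$snapshots)]] <- final
  if (!is.null(traj$metrics))
    traj$metrics[nrow(traj$metrics), ] <- tissue_metrics(final)
  traj
}

#' Stage 2: refinement by differential junction tension
#'
#' Continues from the stage-1 endpoint with SC:SC tension above HC:SC and
#' elevated tension on the OHC-facing top-border junctions; the HC/SC
#' area ratio rises as supporting-cell junctions shorten.
#'
#' @param state the stage-1 end state.
#' @inheritParams run_stage1
#' @return a `corti_trajectory`.
#' @export
run_stage2 <- function(state, params = model_params(),
                       cfg = protocol_config()) {
  p2 <- stage2_params(params)
  advance(state, p2, cfg$steps_stage2, record_every = cfg$record_every,
          differentiate = TRUE, hc_cap = attr(state, "hc_cap") %||% Inf,
          collect_metrics = cfg$collect_metrics, label = "stage2")
}

#' Full two-stage protocol from a fresh initial condition
#'
#' @param seed integer seed covering every source of randomness.
#' @inheritParams run_stage1
#' @param spec a [region_spec()].
#' @return a `corti_trajectory` spanning both stages (snapshot steps
#'   continue across the stage boundary).
#' @export
run_full <- function(seed = 1, spec = region_spec(),
                     params = model_params(), cfg = protocol_config()) {
  state <- init_tissue(spec, params, seed = seed,
                       disorder_cycles = cfg$disorder_cycles,
                       relax_steps = cfg$relax_steps)
  t1 <- run_stage1(state, params, cfg)
  t2 <- run_stage2(t1$final, params, cfg)
  out <- concat_trajectories(t1, t2, label = "full")
  out
}

#' Blebbistatin protocol
#'
#' From a stage-2 endpoint, applies the NMII-inhibition overrides and
#' records the HC/SC area-ratio series, which the model predicts to
#' decrease.
#'
#' @param state a stage-2 end state.
#' @inheritParams run_stage1
#' @param control run without overrides (control arm).
#' @return a `corti_trajectory`.
#' @export
run_blebbistatin <- function(state, params = model_params(),
                             cfg = protocol_config(), control = FALSE) {
  p <- stage2_params(params)
  if (!control) p <- blebbistatin_params(p)
  advance(state, p, cfg$steps_blebbistatin,
          record_every = cfg$record_every, differentiate = FALSE,
          collect_metrics = cfg$collect_metrics,
          label = if (control) "blebbistatin_control" else "blebbistatin")
}

#' Single-cell ablation protocol
#'
#' Spikes the contractility of the target cell by `spike` so that it
#' shrinks through forced T1s and delaminates, mimicking laser ablation.
#' The first-ring neighbors are frozen at ablation time and their
#' relative area change is reported at the end of the schedule.
#'
#' @param state a stage-2 end state.
#' @param target id of an alive interior cell.
#' @inheritParams run_stage1
#' @param spike contractility multiplier for the target.
#' @return a `corti_trajectory` with extra fields: `neighbor_change`
#'   (tibble id, class, area_before, area_after, rel_change) and
#'   `ablated` (logical: was the target removed by a T2).
#' @export
run_ablation <- function(state, target, params = model_params(),
                         cfg = protocol_config(), spike = 100) {
  stopifnot(state$alive[target])
  p <- stage2_params(params)
  p$t2_extra_cells <- target
  st <- state
  st$Gamma_scale[target] <- spike
  ad <- cell_adjacency(st)
  nb <- unique(c(ad[ad[, 1] == target, 2], ad[ad[, 2] == target, 1]))
  g0 <- tissue_geometry(st)
  traj <- advance(st, p, cfg$steps_ablation,
                  record_every = cfg$record_every, differentiate = FALSE,
                  collect_metrics = FALSE, label = "ablation")
  g1 <- tissue_geometry(traj$final)
  after <- g1$area[nb]
  after[!traj$final$alive[nb]] <- 0        # a delaminated neighbor closed fully
  after[!is.finite(after) | after < 0] <- NA_real_
  traj$neighbor_change <- tibble::tibble(
    id = nb, class = st$class[nb],
    area_before = g0$area[nb], area_after = after,
    rel_change = (after - g0$area[nb]) / g0$area[nb])
  traj$ablated <- any(traj$events$kind == "T2" &
                        traj$events$cells == as.character(target))
  traj
}

#' Alternative (adhesion-only) model protocol
#'
#' Runs the full schedule from the given initial state with only
#' differential tension active (no shear, compression or repulsion, and
#' no HC/SC mechanical asymmetry), for comparison against the original
#' model.
#'
#' @param state an initialized `corti_tissue` (same initializer as the
#'   original model for paired comparisons).
#' @inheritParams run_stage1
#' @return a `corti_trajectory`.
#' @export
run_alternative <- function(state, params = model_params(),
                            cfg = protocol_config()) {
  p <- alternative_params(params)
  traj <- advance(state, p, cfg$steps_alternative,
                  record_every = cfg$record_every, differentiate = TRUE,
                  hc_cap = attr(state, "hc_cap") %||% Inf,
                  collect_metrics = cfg$collect_metrics,
                  label = "alternative")
  final <- label_top_boundary(traj$final)
  traj$final <- final
  traj$snapshots[[length(traj$snapshots)]] <- final
  if (!is.null(traj$metrics))
    traj$metrics[nrow(traj$metrics), ] <- tissue_metrics(final)
  traj
}

#' Parameter sweep over the two-stage protocol
#'
#' Re-runs the full protocol with each listed parameter scaled by each
#' factor and collects the end-state order parameters.
#'
#' @param parameters character vector of scalar parameter names; per-class
#'   entries use `"alpha.HC"` style keys.
#' @param factors multiplicative factors (default `c(0.5, 1, 1.5)`).
#' @param seed seed used for every run (paired design).
#' @inheritParams run_full
#' @return a tibble with one row per (parameter, factor) pair and the
#'   end-state metrics.
#' @export
parameter_sweep <- function(parameters = c("sigma", "D", "eta", "zeta"),
                            factors = c(0.5, 1, 1.5), seed = 1,
                            spec = region_spec(), params = model_params(),
                            cfg = protocol_config()) {
  grid <- expand.grid(parameter = parameters, factor = factors,
                      stringsAsFactors = FALSE)
  rows <- purrr::pmap(grid, function(parameter, factor) {
    p <- scale_param(params, parameter, factor)
    traj <- run_full(seed, spec, p, cfg)
    dplyr::bind_cols(tibble::tibble(parameter = parameter, factor = factor),
                     glance(traj)[-1])
  })
  dplyr::bind_rows(rows)
}

scale_param <- function(params, name, factor) {
  if (grepl(".", name, fixed = TRUE)) {
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    params[[parts[1]]][[parts[2]]] <- params[[parts[1]]][[parts[2]]] * factor
  } else if (name %in% names(params) && is.numeric(params[[name]]) &&
             length(params[[name]]) == 1) {
    params[[name]] <- params[[name]] * factor
  } else abort_cfg("unknown sweep parameter", name)
  validate_params(params)
  params
}
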