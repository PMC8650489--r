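#' Construct a block task design
#'
#' Builds the volume-level task mask for a blocked fMRI paradigm in which each
#' block consists of a task phase followed by a rest phase, repeated
#' `n_blocks` times. Defaults reproduce a 15-block 30 s tapping / 30 s rest
#' design sampled at TR = 2.5 s, i.e. 360 volumes of which 180 are task.
#'
#' @param n_blocks Number of task+rest blocks.
#' @param task_s Duration of the task phase of each block, seconds.
#' @param rest_s Duration of the rest phase, seconds.
#' @param tr_s Repetition time (one volume), seconds. Both `task_s` and
#'   `rest_s` must be integer multiples of `tr_s`.
#' @return An object of class `task_design`: a list with `n_blocks`, `task_s`,
#'   `rest_s`, `tr_s`, `n_volumes` and `task_mask` (logical, `TRUE` = task
#'   volume, task-first within each block).
#' @examples
#' d <- make_block_design(15, 30, 30, 2.5)
#' d$n_volumes       # 360
#' sum(d$task_mask)  # 180
#' @export
make_block_design <- function(n_blocks = 15, task_s = 30, rest_s = 30,
                              tr_s = 2.5) {
  stopifnot_scalar_count(n_blocks, "n_blocks")
  if (tr_s <= 0) stop("`tr_s` must be positive", call. = FALSE)
  for (nm in c("task_s", "rest_s")) {
    v <- get(nm)
    r <- v / tr_s
    if (!is_near_integer(r))
      stop(sprintf(
        "`%s` (%g s) is not a multiple of tr_s (%g s): remainder %g s",
        nm, v, tr_s, v - floor(r) * tr_s), call. = FALSE)
  }
  n_task <- as.integer(round(task_s / tr_s))
  n_rest <- as.integer(round(rest_s / tr_s))
  mask <- rep(rep(c(TRUE, FALSE), times = c(n_task, n_rest)), n_blocks)
  structure(list(
    n_blocks = as.integer(n_blocks), task_s = task_s, rest_s = rest_s,
    tr_s = tr_s, n_volumes = length(mask), task_mask = mask
  ), class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf(
    "Block task design: %d blocks of %gs task + %gs rest at TR=%gs (%d volumes, %d task)\n",
    x$n_blocks, x$task_s, x$rest_s, x$tr_s, x$n_volumes, sum(x$task_mask)))
  invisible(x)
}

#' Describe planted modular structure for a synthetic cohort
#'
#' Specifies the community structure that [simulate_subject()] plants in the
#' ROI signals: an affiliation vector assigning each ROI to a module, a
#' within-module coupling amplitude, a between-module leakage amplitude
#' carried by a single global latent, observation noise, and optional
#' per-group overrides (coupling deltas and a set of "inactive" ROIs that are
#' downgraded to pure noise, emulating regions a group fails to recruit).
#'
#' @param affiliation Integer module index per ROI (values `1..M`).
#' @param within_coupling Amplitude of the module latent, in `[0, 1)`.
#' @param between_coupling Amplitude of the shared global latent, in
#'   `[0, within_coupling]`.
#' @param noise_sd Standard deviation of the additive Gaussian observation
#'   noise (signal units).
#' @param group_effects Named list (one entry per group label) of overrides;
#'   each entry may contain `within_coupling`, `between_coupling` and
#'   `inactive_rois` (integer ROI indices simulated as pure noise).
#' @return An object of class `planted_structure`.
#' @export
planted_structure <- function(affiliation, within_coupling = 0.7,
                              between_coupling = 0.1, noise_sd = 1,
                              group_effects = list()) {
  affiliation <- as.integer(affiliation)
  if (anyNA(affiliation) || any(affiliation < 1))
    stop("`affiliation` must assign every ROI a module index >= 1", call. = FALSE)
  if (within_coupling < 0 || within_coupling >= 1)
    stop("`within_coupling` must be in [0, 1)", call. = FALSE)
  if (between_coupling < 0 || between_coupling > within_coupling)
    stop("`between_coupling` must be in [0, within_coupling]", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  for (g in names(group_effects)) {
    ge <- group_effects[[g]]
    bad <- setdiff(names(ge), c("within_coupling", "between_coupling", "inactive_rois"))
    if (length(bad))
      stop(sprintf("unknown group_effects fields for group '%s': %s",
                   g, paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(
    affiliation = affiliation, within_coupling = within_coupling,
    between_coupling = between_coupling, noise_sd = noise_sd,
    group_effects = group_effects
  ), class = "planted_structure")
}

#' Specify a synthetic cohort
#'
#' Bundles everything [simulate_cohort()] needs: group sizes, parcellation
#' size, the task design, planted structure, motion-artifact parameters and a
#' master seed. Defaults emulate the study design the pipeline targets:
#' two groups of 26 and 20 subjects, 212 ROIs, 360 volumes at TR = 2.5 s.
#'
#' @param n_per_group Named integer vector of subjects per group, e.g.
#'   `c(control = 26, patient = 20)`.
#' @param n_rois Number of ROIs.
#' @param design A [make_block_design()] object.
#' @param structure A [planted_structure()] object (affiliation length must
#'   equal `n_rois`).
#' @param motion_spike_rate Per-volume probability of a motion spike.
#' @param motion_spike_mm Differential movement of a spike, mm (set above the
#'   censoring threshold to exercise the censoring path).
#' @param seed Master seed; all per-subject randomness derives from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(control = 26, patient = 20),
                        n_rois = 212,
                        design = make_block_design(),
                        structure = planted_structure(
                          affiliation = rep_len(1:3, n_rois)),
                        motion_spike_rate = 0.02,
                        motion_spike_mm = 1.0,
                        seed = 1L) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group))))
    stop("`n_per_group` must be a named vector of group sizes", call. = FALSE)
  if (any(n_per_group < 1) || any(n_per_group != round(n_per_group)))
    stop("group sizes must be positive integers", call. = FALSE)
  stopifnot_scalar_count(n_rois, "n_rois")
  stopifnot(inherits(design, "task_design"), inherits(structure, "planted_structure"))
  if (length(structure$affiliation) != n_rois)
    stop("structure$affiliation length must equal n_rois", call. = FALSE)
  if (motion_spike_rate < 0 || motion_spike_rate > 1)
    stop("`motion_spike_rate` must be in [0, 1]", call. = FALSE)
  if (motion_spike_mm < 0) stop("`motion_spike_mm` must be >= 0", call. = FALSE)
  structure(list(
    n_per_group = setNames(as.integer(n_per_group), names(n_per_group)),
    n_rois = as.integer(n_rois), design = design, structure = structure,
    motion_spike_rate = motion_spike_rate, motion_spike_mm = motion_spike_mm,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Resolve group-specific couplings / inactive set from a planted_structure.
group_params <- function(structure, group) {
  ge <- structure$group_effects[[group]]
  list(
    within = if (!is.null(ge$within_coupling)) ge$within_coupling else structure$within_coupling,
    between = if (!is.null(ge$between_coupling)) ge$between_coupling else structure$between_coupling,
    inactive = if (!is.null(ge$inactive_rois)) as.integer(ge$inactive_rois) else integer(0)
  )
}

#' Simulate one subject's ROI time series and motion trace
#'
#' Each module `m` has an i.i.d. standard-Gaussian latent signal active only
#' during task volumes; a shared global latent leaks across modules. ROI `i`
#' in module `m` observes
#' `x_i(t) = task(t) * (w * z_m(t) + b * g(t)) + noise_sd * eps_i(t)`
#' with `w = within_coupling` and `b = between_coupling`. Inactive ROIs (per
#' group effects) are pure noise. The motion trace is a low-amplitude baseline
#' with spikes of `motion_spike_mm` at Bernoulli(`motion_spike_rate`) volumes.
#'
#' @param spec A [cohort_spec()].
#' @param group Group label (must be a name of `spec$n_per_group`).
#' @param subject_seed Integer; combined with `spec$seed`, fully determines
#'   the subject's data.
#' @return A list with `ts` (a [roi_timeseries()]) and `motion` (numeric
#'   vector, mm per TR).
#' @export
simulate_subject <- function(spec, group, subject_seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!group %in% names(spec$n_per_group))
    stop(sprintf("unknown group '%s'", group), call. = FALSE)
  pars <- group_params(spec$structure, group)
  n_vol <- spec$design$n_volumes
  n_roi <- spec$n_rois
  task <- as.numeric(spec$design$task_mask)
  aff <- spec$structure$affiliation
  with_seed(mix_seed(spec$seed, subject_seed), {
    n_mod <- max(aff)
    z <- matrix(stats::rnorm(n_mod * n_vol), n_mod, n_vol)   # module latents
    g_lat <- stats::rnorm(n_vol)                             # shared latent
    signal <- pars$within * z[aff, , drop = FALSE] +
      pars$between * matrix(g_lat, n_roi, n_vol, byrow = TRUE)
    signal <- sweep(signal, 2L, task, `*`)
    if (length(pars$inactive)) signal[pars$inactive, ] <- 0
    values <- signal + spec$structure$noise_sd *
      matrix(stats::rnorm(n_roi * n_vol), n_roi, n_vol)
    motion <- stats::runif(n_vol, 0, 0.2)
    spikes <- stats::runif(n_vol) < spec$motion_spike_rate
    motion[spikes] <- spec$motion_spike_mm
    list(
      ts = roi_timeseries(values, roi_names = default_roi_names(n_roi),
                          tr_s = spec$design$tr_s),
      motion = motion
    )
  })
}

#' Simulate a full cohort
#'
#' Runs [simulate_subject()] once per subject with per-subject seeds derived
#' deterministically from the spec's master seed, so the same spec always
#' yields a bit-identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cohort`; each element has `id`, `group`, `ts`,
#'   `motion`.
#' @examples
#' spec <- cohort_spec(n_per_group = c(A = 2, B = 1), n_rois = 12,
#'                     design = make_block_design(2, 10, 10, 2.5),
#'                     structure = planted_structure(rep_len(1:3, 12)))
#' coh <- simulate_cohort(spec)
#' vapply(coh, `[[`, "", "group")
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(names(spec$n_per_group), times = spec$n_per_group)
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    sub <- simulate_subject(spec, groups[i], subject_seed = i)
    out[[i]] <- list(
      id = sprintf("sub-%03d", i), group = groups[i],
      ts = sub$ts, motion = sub$motion)
  }
  class(out) <- "cohort"
  out
}

default_roi_names <- function(n) sprintf("ROI%03d", seq_len(n))

#' Generate a labeled atlas volume fixture
#'
#' Produces a small 3D integer label array standing in for a brain
#' parcellation: `n_cortical + n_subcortical + n_cerebellar` ROIs, each owning
#' at least two voxels, label 0 as background. ROI names carry compartment
#' prefixes (`ctx`/`sub`/`cbl`). This is a synthetic fixture for exercising
#' the ROI-extraction path; it has no anatomical meaning.
#'
#' @param n_cortical,n_subcortical,n_cerebellar ROI counts per compartment.
#' @param grid_shape Integer vector of 3 voxel dimensions.
#' @param seed Seed controlling the voxel assignment.
#' @return A list with `labels` (3D integer array) and `roi_names`
#'   (character, ordered by ascending label).
#' @export
make_atlas_fixture <- function(n_cortical = 142, n_subcortical = 36,
                               n_cerebellar = 34, grid_shape = c(24, 24, 24),
                               seed = 1L) {
  n_roi <- n_cortical + n_subcortical + n_cerebellar
  if (n_roi < 1) stop("need at least one ROI", call. = FALSE)
  if (length(grid_shape) != 3L)
    stop("`grid_shape` must have three dimensions", call. = FALSE)
  n_vox <- prod(grid_shape)
  if (2 * n_roi > n_vox)
    stop(sprintf("grid of %d voxels cannot hold %d ROIs of >= 2 voxels each",
                 n_vox, n_roi), call. = FALSE)
  with_seed(seed, {
    # Give every ROI two guaranteed voxels, then spread the remainder.
    perm <- sample.int(n_vox)
    lab <- integer(n_vox)
    lab[perm[seq_len(2 * n_roi)]] <- rep(seq_len(n_roi), each = 2)
    rest <- perm[-seq_len(2 * n_roi)]
    if (length(rest))
      lab[rest] <- sample.int(n_roi + 1L, length(rest), replace = TRUE) - 1L
    prefixes <- rep(c("ctx", "sub", "cbl"),
                    times = c(n_cortical, n_subcortical, n_cerebellar))
    idx <- unlist(lapply(c(n_cortical, n_subcortical, n_cerebellar), seq_len))
    list(labels = array(lab, dim = grid_shape),
         roi_names = sprintf("%s%03d", prefixes, idx))
  })
}

#' Cohort preset emulating the writer's cramp study design
#'
#' Returns a [cohort_spec()] at the scale of the motivating study: 212 ROIs,
#' 360 volumes (15 blocks of 30 s tapping / 30 s rest at TR = 2.5 s), 26
#' control and 20 patient subjects, three planted modules. The patient group
#' carries a stronger within-module coupling (driving higher clustering) and
#' an inactive-ROI set (driving a smaller recruited-node count), mirroring
#' the qualitative group effects the inference stage is meant to detect.
#'
#' @param seed Master seed for the cohort.
#' @param n_rois,n_inactive_patient Parcellation size and number of patient
#'   inactive ROIs.
#' @return A `cohort_spec`.
#' @export
wc_study_preset <- function(seed = 1L, n_rois = 212, n_inactive_patient = 40) {
  affiliation <- rep_len(1:3, n_rois)
  inactive <- seq(2L, by = 5L, length.out = n_inactive_patient)
  inactive <- inactive[inactive <= n_rois]
  cohort_spec(
    n_per_group = c(control = 26, patient = 20),
    n_rois = n_rois,
    design = make_block_design(15, 30, 30, 2.5),
    structure = planted_structure(
      affiliation = affiliation,
      within_coupling = 0.55, between_coupling = 0.1, noise_sd = 1,
      group_effects = list(
        patient = list(within_coupling = 0.8, inactive_rois = inactive))),
    motion_spike_rate = 0.02, motion_spike_mm = 1.0,
    seed = seed)
}
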