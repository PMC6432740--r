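#' Emotion labels and design intensity levels
#'
#' The five emotional expressions used in the face experiments, and the ten
#' morph-intensity levels of the balanced design, spanning 10% to 91% in
#' equal steps.
#'
#' @return Character vector of emotions / numeric vector of levels.
#' @export
emotion_labels <- function() c("angry", "disgusted", "fearful", "happy", "sad")

#' @rdname emotion_labels
#' @export
expression_intensity_levels <- function() seq(10, 91, length.out = 10)

#' Generating model for synthetic responses
#'
#' Forward-model parameters used by [generate_responses()]. Faces and
#' gratings draw on separate memory resources: the expression resource is
#' shared among the faces in an array, while the orientation resource is
#' shared among the gratings plus — via the load weight
#' `face_orientation_load` (w) — the faces, which automatically consume
#' orientation resource because a face carries low-level orientation
#' structure. This dual-resource rule produces the asymmetry in mixed
#' arrays: an added face inflates grating errors, but added gratings leave
#' expression errors untouched.
#'
#' Default gains sit at interior points of the fitting grids, are ordered
#' happy > disgusted > angry > fearful > sad (the precision ordering
#' recovered for real expressions, with a factor 3 between the extremes),
#' and together with the default face tuning width put simulated recall in
#' the empirically observed variability range (error SD roughly 3-5%
#' intensity at one face, 10-16% at five), where boundary truncation
#' produces the characteristic inward bias at extreme target intensities.
#'
#' @param gain_emotions Named positive vector of per-emotion gain constants.
#' @param width_face Tuning width for expression intensity (% intensity).
#' @param gain_orientation,width_orientation Gain constant and tuning width
#'   (doubled-angle radians) for grating orientation.
#' @param face_orientation_load w in `[0, 1]`: fraction of one
#'   orientation-resource slot consumed by each face.
#' @return An object of class `"generating_model"`.
#' @export
generating_model <- function(gain_emotions = c(angry = 16, disgusted = 20,
                                               fearful = 13, happy = 24,
                                               sad = 8),
                             width_face = 8,
                             gain_orientation = 12,
                             width_orientation = 0.35,
                             face_orientation_load = 1) {
  stopifnot(all(gain_emotions > 0), width_face > 0,
            gain_orientation > 0, width_orientation > 0,
            face_orientation_load >= 0, face_orientation_load <= 1,
            all(emotion_labels() %in% names(gain_emotions)))
  structure(list(gain_emotions = gain_emotions, width_face = width_face,
                 gain_orientation = gain_orientation,
                 width_orientation = width_orientation,
                 face_orientation_load = face_orientation_load),
            class = "generating_model")
}

new_trial_rows <- function(participant, experiment, block, trial, set_size,
                           item_kind, emotion, identity, target, probed) {
  tibble::tibble(participant = participant, experiment = experiment,
                 block = block, trial = trial, set_size = set_size,
                 item_kind = item_kind, emotion = emotion,
                 identity = identity, target = target,
                 response = NA_real_, probed = probed)
}

#' Balanced face-expression design (Experiment 1A structure)
#'
#' Per participant: five 600-trial blocks at set sizes 1 to 5. Within each
#' block the probes are fully balanced: each of 60 face identities is
#' probed 10 times, twice with each of the five emotions — once with an
#' intensity below 50% and once above — with targets drawn from the ten
#' design levels (10% to 91%), each level probed 60 times per block.
#' Non-probed array items get random identities (distinct within a trial),
#' emotions and design-level intensities. Optionally appends the final
#' 300-trial set-size-1 block in which each identity-emotion combination
#' is probed once. One row per array item; responses are left empty for
#' [generate_responses()]. Uses the ambient RNG (`set.seed()` for
#' reproducibility).
#'
#' @param n_participants Number of simulated participants.
#' @param include_final_block Append the repeated set-size-1 block.
#' @return A tibble of trial items (columns `participant`, `experiment`,
#'   `block`, `trial`, `set_size`, `item_kind`, `emotion`, `identity`,
#'   `target`, `response`, `probed`).
#' @export
design_exp1a <- function(n_participants = 1, include_final_block = FALSE) {
  stopifnot(n_participants >= 1)
  levels <- expression_intensity_levels()
  emos <- emotion_labels()
  out <- list()
  for (p in seq_len(n_participants)) {
    for (block in 1:5) {
      n <- block # set size equals block index; order effects not simulated
      sched <- do.call(rbind, lapply(emos, function(e) {
        data.frame(identity = rep(1:60, 2), emotion = e,
                   target = c(sample(rep(levels[1:5], 12)),
                              sample(rep(levels[6:10], 12))))
      }))
      sched <- sched[sample(nrow(sched)), ]
      nt <- nrow(sched)
      # item-major matrices, probed item in row 1, distractors below
      id_mat <- rbind(sched$identity,
                      if (n > 1) vapply(sched$identity, function(pid)
                        sample(setdiff(1:60, pid), n - 1), integer(n - 1)))
      emo_mat <- rbind(sched$emotion,
                       if (n > 1) matrix(sample(emos, (n - 1) * nt,
                                                replace = TRUE), nrow = n - 1))
      tar_mat <- rbind(sched$target,
                       if (n > 1) matrix(sample(levels, (n - 1) * nt,
                                                replace = TRUE), nrow = n - 1))
      out[[length(out) + 1]] <- new_trial_rows(
        participant = p, experiment = "1A", block = block,
        trial = rep(seq_len(nt), each = n), set_size = n,
        item_kind = "face", emotion = as.vector(emo_mat),
        identity = as.vector(id_mat), target = as.vector(tar_mat),
        probed = rep(seq_len(n) == 1, nt))
    }
    if (include_final_block) {
      sched <- expand.grid(identity = 1:60, emotion = emos,
                           stringsAsFactors = FALSE)
      sched$target <- sample(rep(levels, 30))
      sched <- sched[sample(nrow(sched)), ]
      out[[length(out) + 1]] <- new_trial_rows(
        participant = p, experiment = "1A", block = 6,
        trial = seq_len(nrow(sched)), set_size = 1, item_kind = "face",
        emotion = sched$emotion, identity = sched$identity,
        target = sched$target, probed = TRUE)
    }
  }
  dplyr::bind_rows(out)
}

#' Grating-orientation design (Experiment 1B structure)
#'
#' Per participant: 600 trials at each of set sizes 1, 3 and 5, arrays of
#' randomly oriented gratings only (orientations uniform on the
#' 180-degree circle), one item probed per trial.
#'
#' @inheritParams design_exp1a
#' @return A tibble of trial items (see [design_exp1a()]).
#' @export
design_exp1b <- function(n_participants = 1) {
  stopifnot(n_participants >= 1)
  out <- list()
  for (p in seq_len(n_participants)) {
    for (bi in seq_along(c(1, 3, 5))) {
      n <- c(1, 3, 5)[bi]
      out[[length(out) + 1]] <- new_trial_rows(
        participant = p, experiment = "1B", block = bi,
        trial = rep(1:600, each = n), set_size = n, item_kind = "grating",
        emotion = NA_character_, identity = NA_integer_,
        target = stats::runif(600 * n, 0, 180),
        probed = rep(seq_len(n) == 1, 600))
    }
  }
  dplyr::bind_rows(out)
}

#' Mixed face-and-grating design (Experiment 1C structure)
#'
#' Every array holds exactly one face plus either one or three gratings;
#' the probed item is drawn uniformly from the array, so both face-probe
#' and grating-probe trials occur. Face emotions are chosen uniformly at
#' random from the five labels, face intensities from the ten design
#' levels, grating orientations uniformly on the circle.
#'
#' @inheritParams design_exp1a
#' @param n_trials_per_composition Trials with one grating and with three
#'   gratings, per participant.
#' @return A tibble of trial items (see [design_exp1a()]).
#' @export
design_exp1c <- function(n_participants = 1, n_trials_per_composition = 300) {
  stopifnot(n_participants >= 1, n_trials_per_composition >= 1)
  levels <- expression_intensity_levels()
  emos <- emotion_labels()
  out <- list()
  for (p in seq_len(n_participants)) {
    trial0 <- 0
    for (n_grating in c(1, 3)) {
      nt <- n_trials_per_composition
      n <- 1 + n_grating
      probed_pos <- sample.int(n, nt, replace = TRUE)
      emo_mat <- rbind(sample(emos, nt, replace = TRUE),
                       matrix(NA_character_, nrow = n_grating, ncol = nt))
      id_mat <- rbind(sample.int(60, nt, replace = TRUE),
                      matrix(NA_integer_, nrow = n_grating, ncol = nt))
      tar_mat <- rbind(sample(levels, nt, replace = TRUE),
                       matrix(stats::runif(n_grating * nt, 0, 180),
                              nrow = n_grating))
      probed_mat <- vapply(probed_pos, function(pp) seq_len(n) == pp,
                           logical(n))
      out[[length(out) + 1]] <- new_trial_rows(
        participant = p, experiment = "1C", block = 1,
        trial = rep(trial0 + seq_len(nt), each = n), set_size = n,
        item_kind = rep(c("face", rep("grating", n_grating)), nt),
        emotion = as.vector(emo_mat), identity = as.vector(id_mat),
        target = as.vector(tar_mat), probed = as.vector(probed_mat))
      trial0 <- trial0 + nt
    }
  }
  dplyr::bind_rows(out)
}

#' Fill in model-generated responses
#'
#' For each probed item the effective memory load is computed per resource
#' — expression resource: the number of faces in the array; orientation
#' resource: the number of gratings plus `face_orientation_load` times the
#' number of faces — and the population model encodes and decodes the
#' probed feature with gain `gamma / N_effective`. Faces use the bounded
#' expression space with the per-emotion gain; gratings the circular
#' orientation space. By default faces are decoded by posterior sampling
#' and gratings by maximum likelihood (the decoders fitted to each task);
#' pass `decoder` to force one decoder for everything.
#'
#' @param design Trial-item table from a `design_exp1*()` function, with
#'   empty responses.
#' @param model A [generating_model()].
#' @param decoder `NULL` (per-kind default), `"ml"` or
#'   `"posterior_sampling"`.
#' @param n_neurons Population size.
#' @return The design with `response` filled in for probed rows.
#' @export
generate_responses <- function(design, model = generating_model(),
                               decoder = NULL, n_neurons = 1000) {
  stopifnot(inherits(model, "generating_model"))
  if (any(!is.na(design$response[design$probed])))
    stop("design already contains responses", call. = FALSE)
  key <- paste(design$participant, design$experiment, design$block,
               design$trial)
  n_face <- stats::ave(design$item_kind == "face", key, FUN = sum)
  n_grat <- stats::ave(design$item_kind == "grating", key, FUN = sum)
  if (any(tapply(design$probed, key, sum) != 1))
    stop("each trial must have exactly one probed item", call. = FALSE)

  design$response <- NA_real_
  for (kind in c("face", "grating")) {
    rows <- which(design$probed & design$item_kind == kind)
    if (length(rows) == 0) next
    if (kind == "face") {
      space <- bounded_space(0, 100)
      width <- model$width_face
      n_eff <- n_face[rows]
      if (any(n_eff < 1)) stop("probed face in a face-free array", call. = FALSE)
      gain_eff <- unname(model$gain_emotions[design$emotion[rows]]) / n_eff
      dec <- if (is.null(decoder)) "posterior_sampling" else decoder
    } else {
      space <- circular_space(180)
      width <- model$width_orientation
      n_eff <- n_grat[rows] + model$face_orientation_load * n_face[rows]
      if (any(n_grat[rows] < 1))
        stop("probed grating in a grating-free array", call. = FALSE)
      gain_eff <- model$gain_orientation / n_eff
      dec <- if (is.null(decoder)) "ml" else decoder
    }
    params <- population_params(space, gain = 1, width = width,
                                n_neurons = n_neurons)
    design$response[rows] <- simulate_responses(
      params, targets = design$target[rows], decoder = dec,
      n_per_target = 1, gain_eff = gain_eff)
  }
  design
}
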