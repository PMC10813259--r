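# Plain-text serialization: laxity profiles and trial datasets as CSV
# (full double precision so round trips are bit-exact), shape and
# surrogate models as JSON, node loops as x,y,z CSV.

.write_precise_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Read and write laxity profiles as CSV
#'
#' Columns `direction`, `flexion_deg`, `torque_Nm`, `rotation_deg`;
#' rotations are written with 17 significant digits so a write/read round
#' trip reproduces the values bit-exactly.
#'
#' @param profile a `laxity_profile` data frame.
#' @param path file path.
#' @return `read_laxity_csv` returns a `laxity_profile`.
#' @export
write_laxity_csv <- function(profile, path) {
  stopifnot(all(c("direction", "flexion_deg", "torque_Nm",
                  "rotation_deg") %in% names(profile)))
  .write_precise_csv(profile[, c("direction", "flexion_deg", "torque_Nm",
                                 "rotation_deg")], path)
  invisible(path)
}

#' @rdname write_laxity_csv
#' @export
read_laxity_csv <- function(path) {
  d <- utils::read.csv(path, colClasses = c("character", "numeric",
                                            "numeric", "numeric"))
  class(d) <- c("laxity_profile", "data.frame")
  d
}

#' Read and write trial datasets as CSV
#'
#' One row per trial: `trial_id`, the 16 input columns, the 40 laxity
#' columns and `ok`. Dataset attributes (shape model, mesh config) are
#' not serialized; re-attach them from their own files if the dataset is
#' to be re-validated.
#'
#' @param dataset a `capsule_trials` data frame.
#' @param path file path.
#' @export
write_trials_csv <- function(dataset, path) {
  .write_precise_csv(as.data.frame(dataset), path)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  class(d) <- c("capsule_trials", "data.frame")
  d
}

#' Read and write attachment node loops as CSV
#'
#' Plain `x,y,z` CSV in mm, one row per node in loop order.
#'
#' @param nodes an [attachment_nodes()].
#' @param path file path.
#' @param side side label used when reading.
#' @export
write_nodes_csv <- function(nodes, path) {
  .write_precise_csv(as.data.frame(nodes$nodes), path)
  invisible(path)
}

#' @rdname write_nodes_csv
#' @export
read_nodes_csv <- function(path, side = c("acetabular", "femoral")) {
  attachment_nodes(as.matrix(utils::read.csv(path)), match.arg(side))
}

#' Read an attachment population from a directory of node CSVs
#'
#' Expects one `<subject>_acetabular.csv` and one `<subject>_femoral.csv`
#' per subject (plain `x,y,z` files as written by [write_nodes_csv()]).
#'
#' @param dir directory path.
#' @return list of pairs suitable for [fit_shape_model()].
#' @export
read_attachment_population <- function(dir) {
  ace <- sort(list.files(dir, "_acetabular\\.csv$", full.names = TRUE))
  if (length(ace) == 0L) stop("no *_acetabular.csv files in ", dir)
  lapply(ace, function(fa) {
    ff <- sub("_acetabular\\.csv$", "_femoral.csv", fa)
    if (!file.exists(ff)) stop("missing femoral file for ", basename(fa))
    list(acetabular = read_nodes_csv(fa, "acetabular"),
         femoral = read_nodes_csv(ff, "femoral"))
  })
}

#' Write an attachment population to a directory of node CSVs
#'
#' @param population list of pairs (as from
#'   [synthetic_attachment_population()]).
#' @param dir directory path (created if needed).
#' @export
write_attachment_population <- function(population, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(population)) {
    id <- sprintf("subject%03d", i)
    write_nodes_csv(population[[i]]$acetabular,
                    file.path(dir, paste0(id, "_acetabular.csv")))
    write_nodes_csv(population[[i]]$femoral,
                    file.path(dir, paste0(id, "_femoral.csv")))
  }
  invisible(dir)
}

#' Read a trial-generation configuration from YAML
#'
#' Recognized keys: `n_trials`, `seed`, `n_lines`, `head_radius`,
#' `head_center`, and an optional `distributions` block overriding
#' `mean` / `sd` / `trunc_sd` per named parameter.
#'
#' @param path YAML file path.
#' @return list with `n_trials`, `seed`, `mesh_config` and `dists`, ready
#'   for [generate_trial_dataset()].
#' @export
read_trial_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  mesh <- default_mesh_config()
  if (!is.null(cfg$n_lines)) mesh$n_lines <- as.integer(cfg$n_lines)
  if (!is.null(cfg$head_radius)) mesh$head_radius <- cfg$head_radius
  if (!is.null(cfg$head_center)) mesh$head_center <- as.numeric(cfg$head_center)
  d <- default_distributions()
  for (nm in names(cfg$distributions)) {
    i <- match(nm, d$name)
    if (is.na(i)) stop("unknown parameter in config: ", nm)
    for (f in intersect(names(cfg$distributions[[nm]]),
                        c("mean", "sd", "trunc_sd")))
      d[i, f] <- cfg$distributions[[nm]][[f]]
  }
  list(n_trials = cfg$n_trials, seed = cfg$seed, mesh_config = mesh,
       dists = d)
}

#' Write a synthetic specimen as a truth-JSON plus laxity CSV pair
#'
#' The laxity CSV holds only the measurable I-E subset; the JSON holds
#' the generating truth (parameters, scores, noise level), so blinded
#' recovery tests can withhold it.
#'
#' @param specimen a [synthetic_specimen()].
#' @param dir output directory (created if needed).
#' @param name file stem (default `"specimen"`).
#' @export
write_specimen <- function(specimen, dir, name = "specimen") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_laxity_csv(specimen$laxity_measured,
                   file.path(dir, paste0(name, "_laxity.csv")))
  truth <- list(stiffness = specimen$true_parameters$stiffness,
                pre_strain = specimen$true_parameters$pre_strain,
                pc_scores = as.numeric(specimen$true_scores),
                noise_sd_deg = specimen$noise_sd_deg)
  jsonlite::write_json(truth, file.path(dir, paste0(name, "_truth.json")),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Serialize a shape model to JSON
#'
#' Stores the mean vector, the retained PC basis, per-mode SDs, variance
#' fractions and node counts at full precision.
#'
#' @param model a [fit_shape_model()] result.
#' @param path file path.
#' @export
write_shape_model_json <- function(model, path) {
  obj <- list(mean_vector = model$mean_vector,
              pc_vectors = model$pc_vectors,
              mode_sd = model$mode_sd,
              variance_fraction = model$variance_fraction,
              n_modes_retained = model$n_modes_retained,
              n_ace = model$n_ace, n_fem = model$n_fem,
              n_subjects = model$n_subjects)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_shape_model_json
#' @export
read_shape_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$pc_vectors <- matrix(as.numeric(obj$pc_vectors),
                           nrow = obj$n_modes_retained)
  obj$scores <- NULL
  class(obj) <- "shape_model"
  obj
}

#' Serialize a trained surrogate to JSON
#'
#' Per-output selected terms and coefficients keyed by predictor name,
#' plus the training metadata (set id, trial count, thresholds).
#'
#' @param model a [capsule_surrogate()].
#' @param path file path.
#' @export
write_surrogate_json <- function(model, path) {
  obj <- list(set_id = model$set$set_id, n_trials = model$n_trials,
              p_enter = model$p_enter, p_remove = model$p_remove,
              predictor_names = model$predictor_names,
              output_range = lapply(seq_len(ncol(model$output_range)),
                                    function(j) model$output_range[, j]),
              output_names = colnames(model$output_range),
              outputs = lapply(model$fits, function(f)
                list(terms = f$terms,
                     coefficients = as.list(f$coefficients))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_surrogate_json
#' @export
read_surrogate_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  fits <- lapply(obj$outputs, function(f)
    list(terms = as.character(unlist(f$terms)),
         coefficients = unlist(f$coefficients)))
  rng <- NULL
  if (!is.null(obj$output_range)) {
    rng <- vapply(obj$output_range, function(v) as.numeric(unlist(v)),
                  numeric(2L))
    colnames(rng) <- as.character(unlist(obj$output_names))
  }
  structure(list(fits = fits, set = training_set_spec(obj$set_id),
                 predictor_names = as.character(unlist(obj$predictor_names)),
                 n_trials = obj$n_trials, p_enter = obj$p_enter,
                 p_remove = obj$p_remove, output_range = rng),
            class = "capsule_surrogate")
}
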