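#' Serialize a microstate model as JSON
#'
#' @param model a `microstate_model`.
#' @param path output path (.json).
#' @param channel_names optional channel names stored with the templates.
#' @return Invisibly, `path`.
#' @export
write_microstate_model <- function(model, path, channel_names = NULL) {
  if (is.null(channel_names)) channel_names <- colnames(model$templates)
  obj <- list(templates = unname(as.data.frame(t(model$templates))),
              class_names = rownames(model$templates),
              channel_names = channel_names,
              gev = model$gev, n_states = model$n_states,
              polarity_invariant = model$polarity_invariant,
              fit_meta = model$fit_meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a microstate model from JSON
#' @param path path written by [write_microstate_model()].
#' @return A `microstate_model`.
#' @export
read_microstate_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tmpl <- t(as.matrix(as.data.frame(obj$templates)))
  rownames(tmpl) <- obj$class_names
  if (!is.null(obj$channel_names)) colnames(tmpl) <- obj$channel_names
  structure(list(templates = tmpl, gev = obj$gev, n_states = obj$n_states,
                 polarity_invariant = obj$polarity_invariant,
                 fit_meta = obj$fit_meta),
            class = "microstate_model")
}

#' Write a label sequence as single-column text with a JSON sidecar
#' @param labels a `label_sequence`.
#' @param path base path (without extension).
#' @return Invisibly, the paths written.
#' @export
write_label_sequence <- function(labels, path) {
  lab_path <- paste0(path, "_labels.txt")
  meta_path <- paste0(path, "_labels.json")
  writeLines(as.character(labels$labels), lab_path)
  jsonlite::write_json(list(sampling_rate = labels$sampling_rate,
                            n_states = labels$n_states),
                       meta_path, auto_unbox = TRUE)
  invisible(c(lab_path, meta_path))
}

#' Read a label sequence written by [write_label_sequence()]
#' @param path base path used when writing.
#' @return A `label_sequence`.
#' @export
read_label_sequence <- function(path) {
  meta <- jsonlite::read_json(paste0(path, "_labels.json"),
                              simplifyVector = TRUE)
  labs <- as.integer(readLines(paste0(path, "_labels.txt")))
  new_label_sequence(labs, meta$sampling_rate, meta$n_states)
}
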