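# Dataset containers and model checkpoints. One serialized container format
# is shared by features, labels and predictions (R serialization, version 3:
# bit-exact round trips); small outputs additionally get TSV mirrors so they
# remain inspectable as plain text.

container_meta <- function(kind, extra = list()) {
  c(list(kind = kind,
         package = "restdnn",
         version = as.character(utils::packageVersion("restdnn"))),
    extra)
}

#' Write a dataset/model container
#'
#' @param object any package object (feature sets, datasets, models).
#' @param path output path (conventionally `.rds`).
#' @param kind short content tag stored in the container metadata.
#' @param config optional provenance record (configuration and seeds that
#'   produced the artifact).
#' @export
write_container <- function(object, path, kind = class(object)[1],
                            config = NULL) {
  saveRDS(list(meta = container_meta(kind, list(config = config)),
               object = object),
          path, version = 3)
  invisible(path)
}

#' Read a dataset/model container
#' @param path container path.
#' @param kind optional expected content tag; mismatch errors.
#' @return the stored object, with the container metadata in attribute
#'   `"container_meta"`.
#' @export
read_container <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("no such container: ", path)
  raw <- readRDS(path)
  if (!is.list(raw) || is.null(raw$meta)) stop("not a container: ", path)
  if (!is.null(kind) && !identical(raw$meta$kind, kind)) {
    stop("container ", path, " holds '", raw$meta$kind, "', expected '",
         kind, "'")
  }
  obj <- raw$object
  attr(obj, "container_meta") <- raw$meta
  obj
}

#' Save / load a model checkpoint
#'
#' Checkpoints hold the architecture spec, the standardizer and every
#' parameter array; reloads are bit-exact.
#' @param model a `base_model`, `tuned_model` or `delta_model`.
#' @param path checkpoint path.
#' @export
save_checkpoint <- function(model, path) {
  write_container(model, path, kind = paste0("checkpoint:", class(model)[1]))
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- read_container(path)
  meta <- attr(obj, "container_meta")
  if (!startsWith(meta$kind, "checkpoint:")) {
    stop(path, " is not a model checkpoint")
  }
  obj
}

#' Write pair predictions as TSV
#' @param pred data frame from [predict_pairs()].
#' @param path output path.
#' @export
write_predictions <- function(pred, path) {
  utils::write.table(format(pred, digits = 17), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# run configuration ----------------------------------------------------------

.run_config_keys <- c("featurize", "label", "train", "finetune", "predict",
                      "analyze", "seed", "paths", "units")

#' Read and validate a YAML run configuration
#'
#' Unknown top-level keys are rejected so typos fail before any compute.
#' @param path YAML file.
#' @return named list of stage configurations.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .run_config_keys)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg
}
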