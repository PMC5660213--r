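#' Save / load a network checkpoint
#'
#' A checkpoint is a single archive (RDS) holding every parameter tensor
#' keyed by layer name — including batch-norm running statistics — plus the
#' architecture and training configuration used, sufficient to reload the
#' model bit-exactly.
#'
#' @param weights A `network_weights` list.
#' @param spec The [architecture_spec()].
#' @param config The [training_config()] (or NULL).
#' @param path Output file path.
#' @param extra Optional named list stored verbatim (e.g. the fold split).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(weights, spec, config = NULL, path,
                            extra = list()) {
  obj <- c(list(weights = weights, spec = spec, config = config,
                package_version = as.character(utils::packageVersion("hsqcsiam"))),
           extra)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint not found: %s", path))
  obj <- readRDS(path)
  if (is.null(obj$weights) || is.null(obj$spec)) {
    stop("file is not a hsqcsiam checkpoint")
  }
  obj
}
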