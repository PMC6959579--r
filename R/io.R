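# Serialization of trained decoder bundles (templates, filters, selected
# features, ensemble weights, filter-bank settings) in the same RDS
# container style as epoch sets.

#' Save / load a trained decoder
#'
#' @param model a [fit_decoder()] object.
#' @param path file path.
#' @return `load_decoder` returns the restored `ssvep_decoder`.
#' @export
save_decoder <- function(model, path) {
  stopifnot(inherits(model, "ssvep_decoder"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_decoder
#' @export
load_decoder <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ssvep_decoder"))
    stop("file does not contain an ssvep_decoder")
  model
}
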