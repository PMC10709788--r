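#' Hyperparameter sweep over a backend's grid
#'
#' Evaluates every point of a backend's declared hyperparameter grid (e.g.
#' training epochs of a neural tabular generator attached through the
#' adapter contract) by generating synthetic data from a development split
#' and scoring it on a held-out real split; settings are ranked by overall
#' fidelity or by TSTR utility. The reference copula backend declares an
#' empty grid, so sweeping it is a no-op with a notice.
#'
#' @param ds Original data ([tabular_dataset()]).
#' @param backend Backend contract (see [generator_backend()]); its `fit`
#'   must accept `(ds, ...)` with the grid's parameter names.
#' @param criterion `"fidelity"` (overall score) or `"utility"` (mean AUC).
#' @param total Synthetic rows per evaluated setting.
#' @param classifier Adapter used when `criterion = "utility"`.
#' @param seeds TSTR seeds when `criterion = "utility"`.
#' @param train_fraction,split_seed Held-out split control.
#' @return `NULL` (with a message) for an empty grid; otherwise a data
#'   frame of settings and scores, best first, with the best setting in
#'   attribute `"best"`.
#' @export
backend_sweep <- function(ds, backend, criterion = c("fidelity", "utility"),
                          total = 1000L, classifier = "rf", seeds = 1:3,
                          train_fraction = 0.7, split_seed = 1L) {
  criterion <- match.arg(criterion)
  backend <- generator_backend(backend)
  if (!length(backend$grid)) {
    message("backend '", backend$name,
            "' declares no hyperparameter grid; nothing to sweep")
    return(invisible(NULL))
  }
  grid <- expand.grid(backend$grid, stringsAsFactors = FALSE)
  split <- stratified_split(ds, train_fraction, split_seed)
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    setting <- as.list(grid[i, , drop = FALSE])
    model <- do.call(backend$fit, c(list(split$train), setting))
    std <- with_seed(split_seed, backend$sample(model, total))
    if (criterion == "fidelity") {
      quality_report(split$validation, std)$overall
    } else {
      tstr_evaluate(std, split$validation, classifier, seeds)$mean_auc
    }
  }, numeric(1))
  out <- cbind(grid, score = scores)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "best") <- as.list(out[1L, setdiff(names(out), "score"),
                                   drop = FALSE])
  out
}
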