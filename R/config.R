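# YAML run configuration: a single file describing the model, loss and
# training sections, mapped onto the typed config constructors.

#' Read a run configuration from YAML
#'
#' Recognized sections (all optional; omitted keys keep their defaults):
#' `model` (channels, grid_base, use_mrdca, use_pg_invfr, use_el_loss),
#' `mrdca` (k, branch_channels, fusion), `pg_invfr` (k, residual,
#' aux_head_weight), `loss` (alpha, beta, class_weights), and `train`
#' (batch_size, epochs, lr, weight_decay, milestones, gamma, seed).
#'
#' @param path YAML file path.
#' @return list with `model` (a [ptv2fr_config()]) and `train`
#'   (a [train_config()]).
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(section, fn) {
    args <- y[[section]]
    if (is.null(args)) fn() else do.call(fn, args)
  }
  mr <- take("mrdca", mrdca_config)
  pg <- take("pg_invfr", pg_config)
  ls <- local({
    args <- y$loss
    if (!is.null(args$class_weights) && identical(args$class_weights, "auto"))
      args$class_weights <- NULL
    if (is.null(args)) loss_config() else do.call(loss_config, args)
  })
  margs <- y$model
  if (is.null(margs)) margs <- list()
  margs$mrdca <- mr; margs$pg <- pg; margs$loss <- ls
  model <- do.call(ptv2fr_config, margs)
  train <- take("train", train_config)
  list(model = model, train = train)
}
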