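weak_to_list <- function(l) {
  list(w1 = unclass(l$w1), b1 = l$b1, w2 = l$w2, b2 = l$b2,
       center = as.numeric(l$center), scale = as.numeric(l$scale),
       diagnostics = l$diagnostics)
}

weak_from_list <- function(z, config) {
  w1 <- do.call(rbind, lapply(z$w1, as.numeric))
  structure(list(w1 = w1, b1 = as.numeric(z$b1), w2 = as.numeric(z$w2),
                 b2 = as.numeric(z$b2[[1]]),
                 center = as.numeric(z$center), scale = as.numeric(z$scale),
                 config = config, diagnostics = z$diagnostics),
            class = "bp_weak")
}

config_to_list <- function(cfg) unclass(cfg)

config_from_list <- function(z) {
  network_config(n_inputs = z$n_inputs, n_hidden = z$n_hidden,
                 n_outputs = z$n_outputs, a_offset = z$a_offset,
                 epochs = z$epochs, learning_rate = z$learning_rate,
                 error_bound = z$error_bound, trainer = z$trainer)
}

ensemble_to_list <- function(object) {
  list(schema = "mirboost-model",
       schema_version = 1L,
       version = object$version,
       seed = object$seed,
       config = config_to_list(object$config),
       class_map = as.list(object$class_map),
       threshold = object$threshold,
       n_train = object$n_train,
       alphas = object$alphas,
       errors = object$errors,
       learners = lapply(object$learners, weak_to_list))
}

ensemble_from_list <- function(z) {
  config <- config_from_list(z$config)
  learners <- lapply(z$learners, weak_from_list, config = config)
  structure(list(learners = learners,
                 alphas = as.numeric(z$alphas),
                 errors = as.numeric(z$errors),
                 weight_trace = NULL,
                 n_rounds = length(learners),
                 class_map = c(negative = z$class_map$negative,
                               positive = z$class_map$positive),
                 threshold = as.numeric(z$threshold),
                 config = config,
                 n_train = z$n_train,
                 seed = as.integer(z$seed),
                 version = z$version),
            class = "bp_adaboost")
}

#' Write a fitted model to JSON
#'
#' Serializes a binary `bp_adaboost` or multi-class `bp_adaboost_mc` fit to a
#' single self-describing JSON document (schema version, network
#' configuration, per-learner weight matrices and scaling parameters,
#' classifier weights, class map, training seed). [read_model()] restores an
#' object whose predictions are identical to the original's.
#'
#' @param object A `bp_adaboost` or `bp_adaboost_mc` fit.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(object, path) {
  payload <- if (inherits(object, "bp_adaboost_mc")) {
    list(schema = "mirboost-model-mc",
         schema_version = 1L,
         version = object$version,
         seed = object$seed,
         classes = object$classes,
         bank = lapply(object$bank, ensemble_to_list))
  } else if (inherits(object, "bp_adaboost")) {
    ensemble_to_list(object)
  } else {
    rlang::abort("not a mirboost model", class = "mirboost_input_error")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path A file written by [write_model()].
#' @return The restored `bp_adaboost` or `bp_adaboost_mc` object.
#' @export
read_model <- function(path) {
  z <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (identical(z$schema, "mirboost-model")) {
    ensemble_from_list(z)
  } else if (identical(z$schema, "mirboost-model-mc")) {
    bank <- lapply(z$bank, ensemble_from_list)
    names(bank) <- unlist(z$classes)
    structure(list(classes = unlist(z$classes), bank = bank,
                   seed = as.integer(z$seed), version = z$version),
              class = "bp_adaboost_mc")
  } else {
    rlang::abort("file is not a mirboost model", class = "mirboost_input_error")
  }
}
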