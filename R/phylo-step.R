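#' Bidirectional stepwise AIC selection for phylogenetic regressions
#'
#' Starting from the intercept-only Pagel's-lambda PGLS, repeatedly tries
#' adding each absent candidate term and dropping each present one, refits
#' with ML lambda, and accepts the single move with the lowest AIC. The
#' search stops when no move improves the AIC. The accepted-move trace is
#' returned so the monotone decrease of AIC can be audited.
#'
#' @param data Species-keyed data frame (see [pgls_fit()]).
#' @param response Name of the response column.
#' @param candidates Character vector of candidate predictor columns.
#' @param tree An `ape::phylo` tree.
#' @param species_col Name of the species identifier column.
#' @return A list of class `phylostep`: `model` (final `pgls` fit),
#'   `formula`, `selected` terms, and `trace` (tibble of accepted steps).
#' @export
phylostep <- function(data, response, candidates, tree,
                      species_col = "species") {
  if (!length(candidates)) abort("no candidate predictors given.")
  fit_terms <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    f <- stats::as.formula(paste0("`", response, "` ~ ", rhs))
    tryCatch(pgls_fit(data, f, tree, lambda = "ML", species_col = species_col),
             error = function(e) NULL)
  }
  current_terms <- character(0)
  current <- fit_terms(current_terms)
  if (is.null(current)) abort("intercept-only model failed to fit.")
  trace <- tibble::tibble(step = 0L, action = "start", term = NA_character_,
                          AIC = current$AIC)
  step_i <- 0L
  repeat {
    moves <- dplyr::bind_rows(
      tibble::tibble(action = "add",
                     term = setdiff(candidates, current_terms)),
      tibble::tibble(action = "drop", term = current_terms)
    )
    if (!nrow(moves)) break
    fits <- purrr::pmap(moves, function(action, term) {
      terms <- if (action == "add") c(current_terms, term)
               else setdiff(current_terms, term)
      fit_terms(terms)
    })
    aics <- purrr::map_dbl(fits, function(f) if (is.null(f)) Inf else f$AIC)
    if (any(is.infinite(aics))) {
      warn("some candidate moves failed to fit (collinear terms?) and were skipped.")
    }
    best <- which.min(aics)
    if (aics[best] >= current$AIC - 1e-8) break
    step_i <- step_i + 1L
    current_terms <- if (moves$action[best] == "add") {
      c(current_terms, moves$term[best])
    } else {
      setdiff(current_terms, moves$term[best])
    }
    current <- fits[[best]]
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step_i, action = moves$action[best], term = moves$term[best],
      AIC = current$AIC
    ))
  }
  structure(
    list(model = current, formula = current$formula,
         selected = current_terms, trace = trace),
    class = "phylostep"
  )
}

#' @export
print.phylostep <- function(x, ...) {
  cat("Stepwise AIC phylogenetic model selection\n")
  print(as.data.frame(x$trace))
  cat("\nFinal model:\n")
  print(x$model)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.phylostep <- function(x, ...) tidy(x$model)

#' @exportS3Method generics::glance
glance.phylostep <- function(x, ...) {
  dplyr::bind_cols(glance(x$model),
                   tibble::tibble(n_steps = max(x$trace$step)))
}

#' Exhaustive AIC search over all candidate subsets
#'
#' Fits every subset of the candidate terms and returns the AIC table.
#' Exponential in the number of candidates; intended as a certificate for
#' [phylostep()] on small candidate sets.
#'
#' @inheritParams phylostep
#' @return A tibble with one row per model: `terms`, `AIC`, sorted by AIC.
#' @export
pgls_all_subsets <- function(data, response, candidates, tree,
                             species_col = "species") {
  subsets <- purrr::map(0:length(candidates), function(k) {
    utils::combn(candidates, k, simplify = FALSE)
  })
  subsets <- purrr::flatten(subsets)
  purrr::map_dfr(subsets, function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    f <- stats::as.formula(paste0("`", response, "` ~ ", rhs))
    fit <- tryCatch(
      pgls_fit(data, f, tree, lambda = "ML", species_col = species_col),
      error = function(e) NULL
    )
    tibble::tibble(
      terms = paste(rhs),
      AIC = if (is.null(fit)) NA_real_ else fit$AIC
    )
  }) |>
    dplyr::arrange(.data$AIC)
}
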