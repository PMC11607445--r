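#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted treatment-effect CDE model
#'
#' Returns the per-epoch training history (stage, epoch, training objective,
#' validation outcome loss).
#'
#' @param x A trained [tecde_model()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy tecde_model
#' @export
tidy.tecde_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(stage = character(), epoch = integer(),
                          train_objective = numeric(), val_outcome = numeric()))
  }
  x$history
}

#' Glance at a fitted treatment-effect CDE model
#'
#' @param x A [tecde_model()].
#' @param ... Unused.
#' @return A one-row tibble with model dimensions, parameter count and final
#'   validation losses per stage.
#' @method glance tecde_model
#' @export
glance.tecde_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(g) sum(vapply(g, length, 1L)), 1L))
  h <- x$history
  last_val <- function(st) {
    if (is.null(h)) return(NA_real_)
    v <- h$val_outcome[h$stage == st]
    if (length(v)) min(v) else NA_real_
  }
  tibble::tibble(
    latent_dim = x$dims$P, n_vars = x$dims$K, n_treatments = x$dims$M,
    n_outcomes = x$dims$R, control_channels = x$dims$C, n_parameters = n_par,
    trained = !is.null(x$history),
    val_outcome_encoder = last_val("encoder"),
    val_outcome_decoder = last_val("decoder")
  )
}

#' @export
print.tecde_model <- function(x, ...) {
  g <- glance(x)
  cat("<tecde_model> treatment-effect controlled differential equation\n")
  cat(sprintf("  latent dim %d | %d variables | %d treatments | %d outcomes | %d control channels\n",
              g$latent_dim, g$n_vars, g$n_treatments, g$n_outcomes, g$control_channels))
  cat(sprintf("  %d parameters | %s\n", g$n_parameters,
              if (g$trained) "trained" else "untrained"))
  if (g$trained) {
    cat(sprintf("  best validation outcome loss: encoder %.4f, decoder %.4f\n",
                g$val_outcome_encoder, g$val_outcome_decoder))
  }
  invisible(x)
}

#' @export
print.abx_plan <- function(x, ...) {
  cat("<abx_plan> iterative antibiotic selection\n")
  cat("  decisions at:", paste(x$schedule, collapse = ", "), "h\n")
  sel <- dplyr::filter(x$decisions, .data$selected)
  cat("  decision records:", nrow(sel), "| notifications:", nrow(x$notifications), "\n")
  invisible(x)
}
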