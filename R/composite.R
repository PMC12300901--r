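# Composite logistic features: a logistic regression over a named set of
# raw descriptors whose linear predictor (the logit) is exported as one new
# feature column.

#' Composite feature specification
#'
#' `logistic1` is pre-filled with its published component set: the amino acid
#' composition of Phe (`mer5`), the dipeptide compositions of LR (`kmer195`),
#' RF (`kmer285`) and FN (`kmer92`), the serine term of the series-mode
#' pseudo composition (`PseSC16`) and the net charge (`Charge`). Slots
#' `logistic2`..`logistic15` have no published component lists; supply them
#' via `components` (or a spec TSV) to enable them.
#'
#' @param name Composite name (e.g. `"logistic1"`).
#' @param components Character vector of feature names from the schema.
#' @return A list of class `npp_composite_spec`.
#' @export
composite_spec <- function(name, components) {
  stopifnot(is.character(name), length(name) == 1L, length(components) >= 1L)
  structure(list(name = name, components = components),
            class = "npp_composite_spec")
}

#' @rdname composite_spec
#' @export
logistic1_spec <- function() {
  composite_spec("logistic1", c("mer5", "kmer195", "kmer285", "kmer92",
                                "PseSC16", "Charge"))
}

#' Read composite specs from a TSV file
#'
#' Format: one row per composite, `name` then tab-separated component names
#' (ragged rows allowed).
#'
#' @param path TSV path.
#' @return List of `npp_composite_spec`.
#' @export
read_composite_specs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    composite_spec(parts[1], parts[-1])
  })
}

# Ridge-penalized logistic regression by iteratively reweighted least
# squares. The penalty (on standardized inputs, intercept unpenalized) is
# always applied for numerical stability and handles separation.
.ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 100L,
                            tol = 1e-10) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Z1 <- cbind(1, Z)
  p <- ncol(Z)
  pen <- diag(c(0, rep(lambda, p)))
  beta <- numeric(p + 1)
  for (it in seq_len(max_iter)) {
    eta <- drop(Z1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(Z1 * w, Z1) + pen
    b <- crossprod(Z1 * w, z)
    new_beta <- drop(solve(A, b))
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  # map back to the raw-feature scale
  b_raw <- beta[-1] / scl
  b0_raw <- beta[1] - sum(beta[-1] * ctr / scl)
  list(intercept = b0_raw, coefficients = b_raw, iterations = it)
}

#' Fit a composite logistic feature
#'
#' Maximum-likelihood logistic fit of the binary label on the named
#' component columns, with a mild ridge penalty (1e-4 on standardized
#' inputs) always applied for numerical stability; the penalty also acts as
#' the fallback under perfect separation. Deterministic for fixed input.
#'
#' @param features Feature tibble (`id` first).
#' @param labels 0/1 labels aligned to rows (1 = neuropeptide).
#' @param spec An [composite_spec()] naming the components.
#' @param lambda Ridge strength on standardized inputs (default 1e-4).
#' @return A list of class `npp_composite_model`: `spec`, `intercept`,
#'   `coefficients` (named), `lambda`, `separated` (logical).
#' @export
fit_composite <- function(features, labels, spec = logistic1_spec(),
                          lambda = 1e-4) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  miss <- setdiff(spec$components, names(features))
  if (length(miss)) {
    stop("component(s) not in schema: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(features[, spec$components, drop = FALSE])
  fit <- .ridge_logistic(X, y, lambda = lambda)
  eta <- fit$intercept + drop(X %*% fit$coefficients)
  separated <- all((eta > 0) == (y == 1)) && min(abs(eta)) > 10
  structure(list(spec = spec, intercept = fit$intercept,
                 coefficients = stats::setNames(fit$coefficients,
                                                spec$components),
                 lambda = lambda, separated = separated),
            class = "npp_composite_model")
}

#' Append a composite feature column
#'
#' The composite value is the linear predictor
#' `beta0 + sum(beta_i * x_i)` (the logit); its logistic transform is the
#' fitted class probability.
#'
#' @param model An `npp_composite_model`.
#' @param features Feature tibble; must contain every component column.
#' @return The feature tibble with one appended column named after the spec;
#'   the schema attribute gains a `composite` entry.
#' @export
apply_composite <- function(model, features) {
  miss <- setdiff(model$spec$components, names(features))
  if (length(miss)) {
    stop("missing component column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(features[, model$spec$components, drop = FALSE])
  val <- model$intercept + drop(X %*% model$coefficients)
  schema <- feature_schema(features)
  features[[model$spec$name]] <- val
  attr(features, "schema") <- dplyr::bind_rows(
    schema, tibble::tibble(name = model$spec$name, family = "composite"))
  features
}

#' @export
tidy.npp_composite_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @export
glance.npp_composite_model <- function(x, ...) {
  tibble::tibble(name = x$spec$name, n_components = length(x$coefficients),
                 lambda = x$lambda, separated = x$separated)
}

#' @export
print.npp_composite_model <- function(x, ...) {
  cat("Composite logistic feature '", x$spec$name, "' (",
      length(x$coefficients), " components",
      if (x$separated) ", separation: ridge fallback" else "", ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}
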