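#' Standardized multiple regression
#'
#' OLS of z-scored `y` on z-scored predictors, complete cases only. The
#' coefficients are standardized path weights (beta); p-values are the
#' usual two-sided t tests.
#'
#' @param y numeric response vector.
#' @param X data frame or matrix of numeric predictors.
#' @return list with `beta` (named), `p` (named), `n` (complete cases used).
#' @export
ols_standardized <- function(y, X) {
  X <- as.data.frame(X)
  cc <- stats::complete.cases(y, X)
  y <- y[cc]; X <- X[cc, , drop = FALSE]
  n <- length(y)
  if (n <= ncol(X) + 1L)
    stop("need more complete cases than predictors + 1", call. = FALSE)
  ys <- as.numeric(scale(y))
  Xs <- as.data.frame(lapply(X, function(v) as.numeric(scale(v))))
  fit <- stats::lm(ys ~ ., data = Xs)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("predictors are collinear; aliased: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  keep <- rownames(sm) != "(Intercept)"
  nm <- names(X)
  list(beta = stats::setNames(sm[keep, 1], nm),
       p = stats::setNames(sm[keep, 4], nm), n = n)
}

#' Backwards elimination of non-significant predictors
#'
#' Starting from the full standardized regression, repeatedly removes the
#' predictor with the largest p-value at or above the threshold and refits,
#' until every survivor is significant (p below the threshold). Removed
#' predictors never re-enter. Ties in the removal p-value are broken by
#' removing the later-positioned (causally later) predictor first. An empty
#' survivor set is a valid outcome.
#'
#' @param y numeric response.
#' @param X data frame of candidate predictors, columns in causal order.
#' @param threshold significance level for retention (default 0.05).
#' @return list with `beta`, `p` (survivors, from the final fit), `n`, and
#'   `removed` (labels in removal order).
#' @export
backwards_eliminate <- function(y, X, threshold = 0.05) {
  X <- as.data.frame(X)
  removed <- character(0)
  n_used <- NA_integer_
  while (ncol(X) > 0L) {
    fit <- ols_standardized(y, X)
    n_used <- fit$n
    if (all(fit$p < threshold))
      return(list(beta = fit$beta, p = fit$p, n = fit$n, removed = removed))
    worst_p <- max(fit$p[fit$p >= threshold])
    cand <- which(fit$p == worst_p)
    drop_idx <- cand[length(cand)]       # tie: remove the causally later one
    removed <- c(removed, names(X)[drop_idx])
    X <- X[, -drop_idx, drop = FALSE]
  }
  list(beta = stats::setNames(numeric(0), character(0)),
       p = stats::setNames(numeric(0), character(0)),
       n = n_used, removed = removed)
}

#' Fit a backwards-elimination path model over causally ordered variables
#'
#' Each variable from the second onward is regressed on all causally prior
#' variables; predictors are backwards-eliminated until every retained path
#' is significant at the threshold. The result is an acyclic "backbone"
#' graph whose edges carry standardized beta weights. Ordinal outcomes are
#' entered as their numeric scores; binary covariates (e.g. sex) may sit at
#' any causal position.
#'
#' @param data data frame of numeric columns.
#' @param order character vector of column names in causal order (at least
#'   two).
#' @param threshold retention significance level (default 0.05).
#' @param stages optional named character vector mapping variables to stage
#'   labels (`"pre"`, `"medschool"`, `"postgrad"`) used when exporting
#'   diagrams.
#' @return object of class `backbone_model`: `edges` data frame (`source`,
#'   `target`, `beta`, `p`, `n`, retained edges only), `order`, `threshold`,
#'   `removal_log`, `stages`.
#' @export
#' @examples
#' set.seed(7)
#' a <- rnorm(300); b <- 0.6 * a + rnorm(300, 0, 0.8)
#' c <- 0.6 * b + rnorm(300, 0, 0.8)
#' fit_backbone(data.frame(a, b, c), order = c("a", "b", "c"))
fit_backbone <- function(data, order = names(data), threshold = 0.05,
                         stages = NULL) {
  if (length(order) < 2L)
    stop("at least two ordered variables are required", call. = FALSE)
  miss <- setdiff(order, names(data))
  if (length(miss))
    stop("variables not in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  usable <- vapply(order, function(v) any(!is.na(data[[v]])), logical(1))
  if (any(!usable)) {
    warning("skipping all-missing variable(s): ",
            paste(order[!usable], collapse = ", "), call. = FALSE)
    order <- order[usable]
  }
  edges <- list(); removal_log <- list()
  for (i in seq_along(order)[-1]) {
    target <- order[i]
    priors <- order[seq_len(i - 1L)]
    res <- backwards_eliminate(data[[target]], data[priors], threshold)
    removal_log[[target]] <- res$removed
    if (length(res$beta))
      edges[[target]] <- data.frame(
        source = names(res$beta), target = target,
        beta = unname(res$beta), p = unname(res$p), n = res$n)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(0), target = character(0),
               beta = numeric(0), p = numeric(0), n = integer(0))
  rownames(edges) <- NULL
  structure(list(edges = edges, order = order, threshold = threshold,
                 removal_log = removal_log, stages = stages,
                 call = match.call()),
            class = "backbone_model")
}

#' @export
print.backbone_model <- function(x, digits = 3, ...) {
  cat(sprintf("Path model over %d ordered variables (P < %g retention)\n",
              length(x$order), x$threshold))
  cat("  order:", paste(x$order, collapse = " -> "), "\n")
  if (nrow(x$edges) == 0L) {
    cat("  no retained paths\n")
  } else {
    e <- x$edges
    e$beta <- round(e$beta, digits)
    e$p <- signif(e$p, 2)
    print(e, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.backbone_model <- function(object, ...) {
  e <- object$edges
  adj <- match(e$source, object$order) + 1L == match(e$target, object$order)
  structure(list(edges = e, n_edges = nrow(e), n_adjacent = sum(adj),
                 n_longrange = sum(!adj), order = object$order,
                 threshold = object$threshold,
                 removal_log = object$removal_log),
            class = "summary.backbone_model")
}

#' @export
print.summary.backbone_model <- function(x, ...) {
  cat(sprintf("Path model: %d retained edges (%d adjacent, %d long-range) at P < %g\n",
              x$n_edges, x$n_adjacent, x$n_longrange, x$threshold))
  if (x$n_edges) print(x$edges, row.names = FALSE)
  invisible(x)
}

#' @export
coef.backbone_model <- function(object, ...) {
  e <- object$edges
  stats::setNames(e$beta, paste(e$source, e$target, sep = "->"))
}

#' @export
plot.backbone_model <- function(x, ...) {
  k <- length(x$order)
  xs <- seq_len(k); ys <- rep(0, k)
  graphics::plot(xs, ys, type = "n", axes = FALSE, xlab = "", ylab = "",
                 xlim = c(0.5, k + 0.5), ylim = c(-1.2, 1.2), ...)
  if (nrow(x$edges)) {
    for (j in seq_len(nrow(x$edges))) {
      i1 <- match(x$edges$source[j], x$order)
      i2 <- match(x$edges$target[j], x$order)
      h <- if (i2 - i1 == 1L) 0 else 0.5 * (i2 - i1) / k
      graphics::curve(h * 4 * (x - i1) * (i2 - x) / (i2 - i1)^2,
                      from = i1, to = i2, add = TRUE,
                      lwd = 0.5 + 5 * abs(x$edges$beta[j]), col = "grey30")
    }
  }
  graphics::points(xs, ys, pch = 22, bg = "lightsteelblue", cex = 4)
  graphics::text(xs, ys - 0.45, x$order, srt = 30, adj = 1, xpd = NA)
  invisible(x)
}

#' Export a path model as a DOT graph description
#'
#' Left-to-right DOT digraph: arrow pen-width is `penwidth_base` times the
#' absolute standardized beta, and nodes are filled by educational stage
#' (pre-medical-school blue, medical-school green, post-graduate purple)
#' when stage labels are available.
#'
#' @param model a `backbone_model`.
#' @param file optional path to write to.
#' @param penwidth_base multiplier for edge pen-width (default 6).
#' @return DOT source as a character scalar (invisibly if `file` given).
#' @export
export_dot <- function(model, file = NULL, penwidth_base = 6) {
  stage_fill <- c(pre = "lightblue", medschool = "palegreen",
                  postgrad = "plum")
  lines <- c("digraph backbone {", "  rankdir=LR;",
             "  node [shape=box, style=filled, fillcolor=white];")
  for (v in model$order) {
    fill <- "white"
    if (!is.null(model$stages) && v %in% names(model$stages)) {
      st <- model$stages[[v]]
      if (st %in% names(stage_fill)) fill <- stage_fill[[st]]
    }
    lines <- c(lines, sprintf('  "%s" [fillcolor=%s];', v, fill))
  }
  if (nrow(model$edges)) {
    for (j in seq_len(nrow(model$edges))) {
      e <- model$edges[j, ]
      lines <- c(lines, sprintf(
        '  "%s" -> "%s" [penwidth=%.3f, label="%.2f"];',
        e$source, e$target, penwidth_base * abs(e$beta), e$beta))
    }
  }
  lines <- c(lines, "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(dot, file)
    return(invisible(dot))
  }
  dot
}
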