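# Annotation evaluation: accuracy, per-class precision/recall/F1, macro-F1
# and best-method-relative scores.

#' Annotation accuracy
#'
#' Proportion of exact label matches, `1/N * sum(I(y_i == yhat_i))`.
#'
#' @param y_true,y_pred label vectors of equal length (`N >= 1`).
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(y_true, y_pred) {
  abort_if(length(y_true) == 0L, "empty input")
  abort_if(length(y_true) != length(y_pred),
           "y_true and y_pred lengths differ")
  mean(as.character(y_true) == as.character(y_pred))
}

#' Macro-F1 and per-class metrics
#'
#' Per class `c` over the class universe `C` (the union of observed true
#' and predicted labels): `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`, with the 0/0
#' convention that an undefined precision, recall or F1 is 0. Macro-F1 is
#' the unweighted mean of per-class F1, so a hallucinated class (predicted
#' but never true) still counts against it.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @return An object of class `metric_report`: list with `accuracy`,
#'   `macro_f1` and `per_class` (tibble: class, precision, recall, f1,
#'   support).
#' @export
macro_f1 <- function(y_true, y_pred) {
  abort_if(length(y_true) == 0L, "empty input")
  abort_if(length(y_true) != length(y_pred),
           "y_true and y_pred lengths differ")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- sort(unique(c(y_true, y_pred)))
  per <- lapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    tibble::tibble(class = cl, precision = prec, recall = rec, f1 = f1,
                   support = sum(y_true == cl))
  })
  per <- do.call(rbind, per)
  structure(list(accuracy = accuracy(y_true, y_pred),
                 macro_f1 = mean(per$f1), per_class = per),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> accuracy %.4f  macro-F1 %.4f (%d classes)\n",
              x$accuracy, x$macro_f1, nrow(x$per_class)))
  print(x$per_class)
  invisible(x)
}

#' @rdname macro_f1
#' @param x a `metric_report`.
#' @param ... unused.
#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) x$per_class

#' @rdname macro_f1
#' @method glance metric_report
#' @export
glance.metric_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_f1 = x$macro_f1,
                 n_classes = nrow(x$per_class),
                 n_cells = sum(x$per_class$support))
}

#' Scores relative to the best method
#'
#' Divides each method's score by the maximum score in the experiment
#' (all-zero inputs return all zeros), as used to compare methods across
#' heterogeneous experiments.
#'
#' @param scores named numeric vector of per-method scores.
#' @return Named numeric vector of relative scores in `[0, 1]`.
#' @export
relative_score <- function(scores) {
  abort_if(length(scores) == 0L, "need at least one method")
  m <- max(scores)
  if (m <= 0) return(setNames(rep(0, length(scores)), names(scores)))
  scores / m
}

#' Plot per-class F1 of a metric report
#'
#' @param object a `metric_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot metric_report
#' @export
autoplot.metric_report <- function(object, ...) {
  df <- object$per_class
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(class, f1), y = f1)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$macro_f1, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "F1",
                  title = sprintf("macro-F1 = %.3f (dashed)",
                                  object$macro_f1)) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Works for both the sequence model (train/valid BCE) and the GAT
#' (cross-entropy curves).
#'
#' @param history tibble with an `epoch` column and one column per curve.
#' @return A ggplot object.
#' @export
plot_training_history <- function(history) {
  df <- as.data.frame(history)
  long <- do.call(rbind, lapply(setdiff(names(df), "epoch"), function(nm) {
    data.frame(epoch = df$epoch, curve = nm, value = df[[nm]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = epoch, y = value, colour = curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "loss") +
    ggplot2::theme_minimal()
}
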