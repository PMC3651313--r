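# Entropy-based (C4.5-style) decision-tree induction for numeric features:
# binary splits at midpoints between sorted distinct values, information gain
# as split criterion (gain ratio optional), minimum leaf size 2, pessimistic
# error-based pruning with confidence factor 0.25 (the documented defaults of
# the common open implementation of the algorithm), stratified k-fold
# cross-validation and pooled confusion matrices.

#' Information entropy of a class distribution (bits)
#'
#' `H = -sum(p_i * log2(p_i))` with `0 * log2(0) == 0`, where `p_i` is the
#' fraction of instances in class i.
#'
#' @param counts non-negative counts (or probabilities) per class
#' @return entropy in bits, between 0 and log2(number of classes)
#' @export
entropy <- function(counts) {
  if (length(counts) == 0 || sum(counts) <= 0) stop("empty class distribution")
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# entropy of each row of a count matrix (vectorised)
entropy_rows <- function(M) {
  tot <- rowSums(M)
  P <- M / ifelse(tot > 0, tot, 1)
  L <- ifelse(P > 0, log2(P), 0)
  -rowSums(P * L)
}

#' Information gain of a binary threshold split
#'
#' Parent entropy minus the instance-weighted entropy of the two children
#' formed by `column <= threshold` / `column > threshold`. A degenerate split
#' (one side empty) has gain 0.
#'
#' @param column numeric feature values
#' @param labels factor (or character) class labels
#' @param threshold split point
#' @return gain in bits (non-negative)
#' @export
information_gain <- function(column, labels, threshold) {
  labels <- factor(labels)
  left <- column <= threshold
  nl <- sum(left)
  n <- length(column)
  if (nl == 0 || nl == n) return(0)
  h <- entropy(table(labels))
  hl <- entropy(table(labels[left]))
  hr <- entropy(table(labels[!left]))
  h - (nl / n) * hl - ((n - nl) / n) * hr
}

# Best split over all features/thresholds; returns NULL if no admissible
# split exists (every feature constant, or the minimum leaf size cannot be
# met). An impure node is split even at zero gain -- the algorithm recurses
# until leaves are pure or unsplittable, and pruning removes unhelpful
# structure afterwards. Ties: first feature in column order, then the
# smallest threshold (the scan visits candidates in that order and replaces
# only on a strict improvement).
best_split <- function(X, y, min_leaf = 2, criterion = c("gain", "gainratio")) {
  criterion <- match.arg(criterion)
  n <- length(y)
  classes <- levels(y)
  h_parent <- entropy(table(y))
  best <- NULL
  best_score <- -Inf
  Y <- outer(y, classes, `==`) * 1
  for (f in seq_along(X)) {
    x <- X[[f]]
    ord <- order(x)
    xs <- x[ord]
    cum <- apply(Y[ord, , drop = FALSE], 2, cumsum)
    cut <- which(diff(xs) > 0)               # boundaries between distinct values
    cut <- cut[cut >= min_leaf & (n - cut) >= min_leaf]
    if (!length(cut)) next
    nl <- cut
    Hl <- entropy_rows(cum[cut, , drop = FALSE])
    Hr <- entropy_rows(sweep(-cum[cut, , drop = FALSE], 2, -cum[n, ]))
    gains <- h_parent - (nl / n) * Hl - ((n - nl) / n) * Hr
    score <- gains
    if (criterion == "gainratio") {
      pl <- nl / n
      si <- -(pl * log2(pl) + (1 - pl) * log2(1 - pl))
      score <- ifelse(si > 0, gains / si, 0)
    }
    i <- which.max(score)
    if (score[i] > best_score + 1e-12) {
      best_score <- score[i]
      best <- list(feature = names(X)[f],
                   threshold = (xs[cut[i]] + xs[cut[i] + 1]) / 2,
                   gain = gains[i], score = score[i])
    }
  }
  best
}

leaf_node <- function(y) {
  counts <- table(y)
  cls <- names(counts)[which.max(counts)]   # ties: first level
  list(type = "leaf", class = cls,
       counts = as.list(stats::setNames(as.integer(counts), names(counts))),
       n = length(y), n_wrong = length(y) - max(counts))
}

grow_tree <- function(X, y, min_leaf, criterion) {
  if (nlevels(droplevels(y)) <= 1 || length(y) < 2 * min_leaf) {
    return(leaf_node(y))
  }
  sp <- best_split(X, y, min_leaf, criterion)
  if (is.null(sp)) return(leaf_node(y))
  left <- X[[sp$feature]] <= sp$threshold
  node <- list(type = "split", feature = sp$feature, threshold = sp$threshold,
               counts = as.list(stats::setNames(as.integer(table(y)),
                                                levels(y))),
               n = length(y),
               left = grow_tree(X[left, , drop = FALSE], y[left],
                                min_leaf, criterion),
               right = grow_tree(X[!left, , drop = FALSE], y[!left],
                                 min_leaf, criterion))
  node
}

# Pessimistic extra-error estimate: upper confidence bound on the binomial
# error rate at confidence factor cf (the classical C4.5 formulation).
add_errs <- function(n, e, cf = 0.25) {
  if (cf > 0.5) return(e * 0)  # no pruning pressure
  if (e < 1) {
    base <- n * (1 - cf^(1 / n))
    if (e == 0) return(base)
    return(base + e * (add_errs(n, 1, cf) - base))
  }
  if (e + 0.5 >= n) return(max(n - e, 0))
  z <- stats::qnorm(1 - cf)
  f <- (e + 0.5) / n
  r <- (f + z^2 / (2 * n) +
          z * sqrt(f / n - f^2 / n + z^2 / (4 * n^2))) / (1 + z^2 / n)
  r * n - e
}

subtree_est_errors <- function(node, cf) {
  if (node$type == "leaf") {
    return(node$n_wrong + add_errs(node$n, node$n_wrong, cf))
  }
  subtree_est_errors(node$left, cf) + subtree_est_errors(node$right, cf)
}

prune_tree <- function(node, cf = 0.25) {
  if (node$type == "leaf") return(node)
  node$left <- prune_tree(node$left, cf)
  node$right <- prune_tree(node$right, cf)
  counts <- unlist(node$counts)
  n <- node$n
  e_leaf <- n - max(counts)
  est_leaf <- e_leaf + add_errs(n, e_leaf, cf)
  est_tree <- subtree_est_errors(node, cf)
  if (est_leaf <= est_tree + 0.1) {
    cls <- names(counts)[which.max(counts)]
    return(list(type = "leaf", class = cls, counts = node$counts,
                n = n, n_wrong = e_leaf))
  }
  node
}

#' Build a C4.5-style decision tree
#'
#' Recursive best-information-gain induction with binary numeric splits at
#' midpoints between sorted distinct values. Growth stops when all remaining
#' instances share a class, no admissible split exists (constant features, or
#' the minimum leaf size cannot be met), or fewer than `2 * min_leaf`
#' instances remain; impure nodes are otherwise always split on the
#' highest-gain candidate, and unhelpful structure is removed afterwards by
#' pessimistic error-estimate pruning (subtree replacement) at confidence
#' factor `cf`.
#'
#' @param X data.frame of numeric features
#' @param y class labels (factor or character)
#' @param min_leaf minimum instances on each side of a split (default 2)
#' @param cf pruning confidence factor (default 0.25; `cf >= 0.5` disables
#'   pruning pressure)
#' @param prune logical, apply pessimistic pruning (default TRUE)
#' @param criterion `"gain"` (default) or `"gainratio"`
#' @return object of class `c45_tree`
#' @export
build_tree <- function(X, y, min_leaf = 2, cf = 0.25, prune = TRUE,
                       criterion = c("gain", "gainratio")) {
  criterion <- match.arg(criterion)
  X <- as.data.frame(X)
  if (!nrow(X)) stop("no training instances")
  if (!all(vapply(X, is.numeric, TRUE))) stop("features must be numeric")
  if (any(!is.finite(as.matrix(X)))) stop("non-finite feature values")
  y <- factor(y)
  root <- grow_tree(X, y, min_leaf, criterion)
  if (prune) root <- prune_tree(root, cf)
  structure(list(root = root, classes = levels(y), features = names(X)),
            class = "c45_tree")
}

route_row <- function(node, row) {
  while (node$type == "split") {
    v <- row[[node$feature]]
    if (is.null(v) || is.na(v)) {
      stop("missing value for feature ", node$feature)
    }
    node <- if (v <= node$threshold) node$left else node$right
  }
  node
}

#' Predict classes (and optionally leaf class distributions) from a tree
#'
#' Rows are routed root-to-leaf; values equal to a threshold go to the
#' `<=` branch.
#'
#' @param object a `c45_tree`
#' @param newdata data.frame with the tree's feature columns
#' @param type `"class"` for labels, `"prob"` for Laplace-smoothed leaf class
#'   distributions
#' @param ... unused
#' @return character vector of classes, or a matrix of probabilities
#' @export
predict.c45_tree <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) {
    stop("missing value for feature ", miss[1])
  }
  leaves <- lapply(seq_len(nrow(newdata)), function(i) {
    route_row(object$root, newdata[i, , drop = FALSE])
  })
  if (type == "class") {
    return(vapply(leaves, `[[`, "", "class"))
  }
  P <- t(vapply(leaves, function(lf) {
    cnt <- stats::setNames(rep(0, length(object$classes)), object$classes)
    cnt[names(lf$counts)] <- unlist(lf$counts)
    (cnt + 1) / sum(cnt + 1)
  }, numeric(length(object$classes))))
  colnames(P) <- object$classes
  P
}

#' @export
print.c45_tree <- function(x, ...) {
  cat(tree_to_text(x), sep = "\n")
  invisible(x)
}

#' Indented text rendering of a tree ("class (n/errors)" leaves)
#' @param tree a `c45_tree`
#' @return character vector, one line per node
#' @export
tree_to_text <- function(tree) {
  rec <- function(node, depth) {
    pad <- strrep("|   ", depth)
    if (node$type == "leaf") {
      return(paste0(pad, node$class, " (", node$n, "/", node$n_wrong, ")"))
    }
    c(paste0(pad, node$feature, " <= ", format(node$threshold)),
      rec(node$left, depth + 1),
      paste0(pad, node$feature, " > ", format(node$threshold)),
      rec(node$right, depth + 1))
  }
  rec(tree$root, 0)
}

# nested-list (JSON-ready) forms
tree_to_list <- function(tree) {
  list(classes = tree$classes, features = tree$features, root = tree$root)
}

tree_from_list <- function(lst) {
  fix <- function(node) {
    node$counts <- lapply(node$counts, as.integer)
    if (node$type == "split") {
      node$left <- fix(node$left)
      node$right <- fix(node$right)
    } else {
      node$n <- as.integer(node$n)
      node$n_wrong <- as.integer(node$n_wrong)
    }
    node
  }
  structure(list(root = fix(lst$root), classes = unlist(lst$classes),
                 features = unlist(lst$features)),
            class = "c45_tree")
}

#' Stratified k-fold cross-validation of the tree classifier
#'
#' Folds are stratified by class; each fold is predicted by a tree trained on
#' the remaining folds, and predictions are pooled into one confusion matrix
#' (rows = true class, columns = predicted class).
#'
#' @param X data.frame of numeric features
#' @param y class labels
#' @param k number of folds (default 10)
#' @param seed RNG seed for the fold assignment
#' @param ... passed to [build_tree()]
#' @return list with `accuracy` (fraction), `confusion` (table), and `folds`
#' @export
cross_validate <- function(X, y, k = 10, seed = 1, ...) {
  y <- factor(y)
  n <- length(y)
  if (k > n) stop("k exceeds the number of instances")
  if (any(table(y) < k)) {
    warning("some classes have fewer than k instances; folds are stratified ",
            "as evenly as the class sizes allow")
  }
  folds <- integer(n)
  rng <- local({set.seed(seed); lapply(split(seq_len(n), y), sample)})
  offset <- 0
  for (idx in rng) {
    folds[idx] <- ((seq_along(idx) + offset - 1) %% k) + 1
    offset <- offset + length(idx)
  }
  pred <- character(n)
  for (fold in sort(unique(folds))) {
    test <- folds == fold
    tree <- build_tree(X[!test, , drop = FALSE], droplevels(y[!test]), ...)
    pred[test] <- predict(tree, X[test, , drop = FALSE])
  }
  confusion <- table(true = y, predicted = factor(pred, levels = levels(y)))
  list(accuracy = mean(pred == as.character(y)), confusion = confusion,
       folds = folds)
}
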