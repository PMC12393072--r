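## Group-structure inference and classification on the corrected, normalized
## channel values: ANOSIM permutation tests on a distance matrix, PCA
## ripeness trajectories with coverage-ellipse stage assignment, and linear
## discriminant classification with confusion matrices.

.featureMatrix <- function(x) {
  if (is(x, "OdorFeatureSet"))
    t(SummarizedExperiment::assay(x, "odor"))
  else as.matrix(x)
}

#' Pairwise distances between readings
#'
#' @param x numeric matrix / data.frame (rows = readings) or an
#'   \code{\link{OdorFeatureSet}}.
#' @param metric \code{"euclidean"} (default) or \code{"bray"}
#'   (Bray-Curtis).
#' @return symmetric distance matrix with zero diagonal and a
#'   \code{"metric"} attribute.
#' @export
pairwiseDistances <- function(x, metric = c("euclidean", "bray")) {
  metric <- match.arg(metric)
  m <- .featureMatrix(x)
  if (nrow(m) < 2L) .stopf("need at least 2 rows")
  if (any(!is.finite(m))) .stopf("non-finite cells in the feature table")
  D <- if (metric == "euclidean") as.matrix(dist(m)) else {
    n <- nrow(m)
    out <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      num <- sum(abs(m[i, ] - m[j, ]))
      den <- sum(abs(m[i, ] + m[j, ]))
      out[i, j] <- out[j, i] <- if (den == 0) 0 else num / den
    }
    out
  }
  dimnames(D) <- list(rownames(m), rownames(m))
  attr(D, "metric") <- metric
  D
}

## all distinct permutations of a label multiset (list of integer vectors)
.multisetPerms <- function(counts) {
  k <- length(counts)
  rec <- function(counts, n) {
    if (n == 0L) return(list(integer(0)))
    out <- list()
    for (l in seq_len(k)) {
      if (counts[l] == 0L) next
      counts[l] <- counts[l] - 1L
      out <- c(out, lapply(rec(counts, n - 1L), function(v) c(l, v)))
      counts[l] <- counts[l] + 1L
    }
    out
  }
  rec(counts, sum(counts))
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group structure on a distance matrix:
#' R = (mean rank of between-group distances - mean rank of within-group
#' distances) / (M/2), with M = n(n-1)/2 and midranks for ties, so that
#' R = 1 when every between-group distance outranks every within-group
#' distance and R ~ 0 under no group structure. The p-value is obtained by
#' relabeling: exactly, by enumerating all distinct relabelings when their
#' number is at most \code{exactLimit}; otherwise by Monte-Carlo
#' permutation with \code{p = (#\{R* >= R\} + 1) / (nPermutations + 1)}.
#'
#' @param d distance matrix (or \code{dist}) as from
#'   \code{\link{pairwiseDistances}}.
#' @param groups group labels, one per reading; every group needs >= 2
#'   members.
#' @param nPermutations Monte-Carlo permutations (default 9999).
#' @param seed integer seed for the permutation stream.
#' @param exactLimit enumeration threshold on the number of distinct
#'   relabelings.
#' @return An \code{\link{AnosimResult}}.
#' @examples
#' x <- rbind(matrix(0, 4, 2), matrix(5, 4, 2)) + 0.01 * matrix(rnorm(16), 8)
#' anosimTest(pairwiseDistances(x), rep(c("a", "b"), each = 4), seed = 1)
#' @export
anosimTest <- function(d, groups, nPermutations = 9999, seed = NULL,
                       exactLimit = 20000) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  g <- as.integer(factor(groups))
  if (length(g) != n) .stopf("'groups' length must match the matrix size")
  counts <- tabulate(g)
  if (length(counts) < 2L) .stopf("need at least 2 groups")
  if (any(counts < 2L))
    .stopf("every group needs at least 2 members (singleton group found)")
  ut <- upper.tri(dm)
  r <- rank(dm[ut])                       # midranks
  ij <- which(ut, arr.ind = TRUE)
  ii <- ij[, 1L]; jj <- ij[, 2L]
  M <- n * (n - 1) / 2
  Rstat <- function(gg) {
    w <- gg[ii] == gg[jj]
    (mean(r[!w]) - mean(r[w])) / (M / 2)
  }
  Robs <- Rstat(g)
  nDistinct <- round(exp(lfactorial(n) - sum(lfactorial(counts))))
  if (nDistinct <= exactLimit) {
    perms <- .multisetPerms(counts)
    Rp <- vapply(perms, Rstat, numeric(1))
    p <- mean(Rp >= Robs - 1e-12)
    new("AnosimResult", statistic = Robs, p_value = p,
        n_permutations = nDistinct, exact = TRUE, seed = NA_real_)
  } else {
    Rp <- withSeed(seed, vapply(seq_len(nPermutations), function(b)
      Rstat(g[sample.int(n)]), numeric(1)))
    p <- (sum(Rp >= Robs - 1e-12) + 1) / (nPermutations + 1)
    new("AnosimResult", statistic = Robs, p_value = p,
        n_permutations = nPermutations, exact = FALSE,
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
  }
}

#' Principal component analysis of odor profiles
#'
#' Column-centered (and by default unit-variance-scaled) eigendecomposition;
#' scores are ordered by decreasing eigenvalue. Channels share units but
#' differ widely in dynamic range, hence the default scaling.
#'
#' @param x numeric matrix (rows = readings) or \code{\link{OdorFeatureSet}}.
#' @param scale scale columns to unit variance (default TRUE); constant
#'   columns are left unscaled with a warning.
#' @return list of class \code{"odorPCA"}: \code{scores}, \code{loadings},
#'   \code{sdev}, \code{explained} (proportion of variance per component),
#'   \code{center}, \code{scale}.
#' @export
pcaFit <- function(x, scale = TRUE) {
  m <- .featureMatrix(x)
  if (nrow(m) < 2L || ncol(m) < 2L) .stopf("need at least 2 rows and 2 columns")
  sc <- FALSE
  if (scale) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      .warnf("constant column(s) left unscaled: %s",
             paste(colnames(m)[sds == 0], collapse = ", "))
      sds[sds == 0] <- 1
    }
    sc <- sds
  }
  p <- prcomp(m, center = TRUE, scale. = sc)
  structure(list(scores = p$x, loadings = p$rotation, sdev = p$sdev,
                 explained = p$sdev^2 / sum(p$sdev^2), center = p$center,
                 scale = p$scale), class = "odorPCA")
}

## Mahalanobis squared distance with a tiny ridge when the covariance is
## numerically singular (collinear day clouds).
.mahal2 <- function(pts, mu, S) {
  if (rcond(S) < 1e-12) S <- S + diag(1e-12 * (sum(diag(S)) / 2 + 1), 2)
  z <- sweep(pts, 2, mu)
  inv <- solve(S)
  rowSums((z %*% inv) * z)
}

## do the level-coverage ellipses of two clouds intersect?
.ellipsesOverlap <- function(mu1, S1, mu2, S2, r2, npts = 360) {
  if (.mahal2(rbind(mu1), mu2, S2) <= r2) return(TRUE)
  if (.mahal2(rbind(mu2), mu1, S1) <= r2) return(TRUE)
  th <- seq(0, 2 * pi, length.out = npts + 1)[-1]
  circ <- rbind(cos(th), sin(th)) * sqrt(r2)
  bnd1 <- t(t(chol(S1)) %*% circ + mu1)
  if (any(.mahal2(bnd1, mu2, S2) <= r2)) return(TRUE)
  bnd2 <- t(t(chol(S2)) %*% circ + mu2)
  any(.mahal2(bnd2, mu1, S1) <= r2)
}

#' Assign ripeness stages from daily score clouds
#'
#' A day's odor signal "overlaps" the cracking day when their coverage
#' ellipses (per-day mean and covariance in PC1-PC2, Mahalanobis radius
#' chi-square quantile with 2 df at \code{level}) intersect. Days before the
#' cracking day that do not overlap it are \code{before_ripening}; days
#' overlapping it (including the cracking day itself) are \code{ripened};
#' later non-overlapping days are \code{after_ripening}. Days with fewer
#' than 3 readings have no defined covariance and are \code{unassigned}
#' with a warning.
#'
#' @param scores matrix of PC scores (first two columns used), e.g.
#'   \code{pcaFit(x)$scores}.
#' @param day per-reading day labels.
#' @param crackingDay the fruit's cracking day (must be among \code{day}).
#' @param level ellipse coverage level (default 0.95).
#' @return data.frame with columns \code{day}, \code{n},
#'   \code{overlaps_cracking}, \code{stage}.
#' @export
assignRipenessStages <- function(scores, day, crackingDay, level = 0.95) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2L) .stopf("need at least 2 score columns")
  if (nrow(scores) != length(day))
    .stopf("'day' length must match the score rows")
  days <- sort(unique(day))
  if (!crackingDay %in% days)
    .stopf("cracking day %s not present in 'day'", format(crackingDay))
  r2 <- qchisq(level, df = 2)
  stats <- lapply(days, function(dd) {
    s <- scores[day == dd, 1:2, drop = FALSE]
    if (nrow(s) < 3L) return(NULL)
    list(mu = colMeans(s), S = cov(s), n = nrow(s))
  })
  names(stats) <- as.character(days)
  if (is.null(stats[[as.character(crackingDay)]]))
    .stopf("cracking day has fewer than 3 readings; stages undefined")
  crack <- stats[[as.character(crackingDay)]]
  out <- data.frame(day = days, n = NA_integer_, overlaps_cracking = NA,
                    stage = NA_character_)
  for (i in seq_along(days)) {
    st <- stats[[i]]
    if (is.null(st)) {
      .warnf("day %s has fewer than 3 readings; stage unassigned",
             format(days[i]))
      out$n[i] <- sum(day == days[i])
      out$stage[i] <- "unassigned"
      next
    }
    out$n[i] <- st$n
    ov <- if (days[i] == crackingDay) TRUE else
      .ellipsesOverlap(st$mu, st$S, crack$mu, crack$S, r2)
    out$overlaps_cracking[i] <- ov
    out$stage[i] <- if (ov) "ripened"
      else if (days[i] < crackingDay) "before_ripening"
      else "after_ripening"
  }
  out
}

#' Fit a linear discriminant model
#'
#' Discriminant axes are the eigenvectors of the pooled within-class
#' covariance inverse times the between-class scatter, solved through a
#' symmetric Cholesky reduction. Axes are L2-normalized and
#' sign-canonicalized (the largest-magnitude coefficient is positive). When
#' the within-class covariance is numerically singular a ridge of
#' \code{1e-8 trace(Sw)/p} is added to its diagonal (with a message) unless
#' \code{ridge = FALSE}, in which case this is a numerical-rank error.
#'
#' @param x numeric matrix (rows = readings) or \code{\link{OdorFeatureSet}}
#'   (whose \code{colData$class} supplies labels when \code{labels} is
#'   missing).
#' @param labels class labels, one per reading.
#' @param priors optional named class priors (default: class frequencies).
#' @param ridge allow the ridge fallback (default TRUE).
#' @return An \code{\link{LDAModel}}.
#' @export
ldaFit <- function(x, labels = NULL, priors = NULL, ridge = TRUE) {
  if (is(x, "OdorFeatureSet") && is.null(labels))
    labels <- SummarizedExperiment::colData(x)$class
  m <- .featureMatrix(x)
  if (is.null(colnames(m))) colnames(m) <- paste0("ch", seq_len(ncol(m)))
  f <- factor(labels)
  k <- nlevels(f); p <- ncol(m); n <- nrow(m)
  if (k < 2L) .stopf("need at least 2 classes")
  if (length(f) != n) .stopf("'labels' length must match rows")
  ng <- table(f)
  if (any(ng < 2L)) .stopf("every class needs at least 2 readings")
  centers <- do.call(rbind, lapply(levels(f), function(l)
    colMeans(m[f == l, , drop = FALSE])))
  rownames(centers) <- levels(f)
  W <- matrix(0, p, p)
  for (l in levels(f)) {
    cm <- sweep(m[f == l, , drop = FALSE], 2, centers[l, ])
    W <- W + crossprod(cm)
  }
  Sw <- W / (n - k)
  grand <- colSums(centers * as.numeric(ng)) / n
  B <- matrix(0, p, p)
  for (l in levels(f)) {
    dv <- centers[l, ] - grand
    B <- B + ng[[l]] * tcrossprod(dv)
  }
  ch <- tryCatch(chol(Sw), error = function(e) NULL)
  if (is.null(ch) || rcond(Sw) < 1e-10) {
    if (!ridge)
      .stopf("within-class covariance is numerically singular (rank error)")
    lambda <- 1e-8 * sum(diag(Sw)) / p
    message(sprintf("ldaFit: adding ridge %.3g to a near-singular ",
                    lambda), "within-class covariance")
    Sw <- Sw + diag(lambda, p)
    ch <- chol(Sw)
  }
  L <- t(ch)
  C <- forwardsolve(L, t(forwardsolve(L, B)))
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  naxes <- min(k - 1L, p)
  axes <- backsolve(ch, e$vectors[, seq_len(naxes), drop = FALSE])
  axes <- apply(axes, 2, function(a) {
    a <- a / sqrt(sum(a^2))
    if (a[which.max(abs(a))] < 0) -a else a
  })
  axes <- matrix(axes, nrow = p,
                 dimnames = list(colnames(m),
                                 paste0("Axis", seq_len(naxes))))
  if (is.null(priors)) priors <- as.numeric(ng) / n
  names(priors) <- levels(f)
  new("LDAModel", scaling = axes, centers = centers, priors = priors,
      channels = colnames(m), svd = e$values[seq_len(naxes)])
}

#' @rdname ldaFit
#' @param scaling channel-by-axis coefficient matrix (for building a model
#'   from externally supplied discriminant functions).
#' @param centers optional class-means matrix (rows = classes); required
#'   for classification, not for projection.
#' @param channels channel names; default the rownames of \code{scaling}.
#' @export
ldaModel <- function(scaling, centers = NULL, priors = NULL,
                     channels = rownames(scaling)) {
  scaling <- as.matrix(scaling)
  if (is.null(channels))
    channels <- paste0("ch", seq_len(nrow(scaling)))
  rownames(scaling) <- channels
  if (is.null(colnames(scaling)))
    colnames(scaling) <- paste0("Axis", seq_len(ncol(scaling)))
  if (is.null(centers)) {
    centers <- matrix(numeric(0), 0, nrow(scaling),
                      dimnames = list(NULL, channels))
    ## validity bounds axes by classes; a projection-only model has none
    centers <- rbind(centers)
  }
  if (is.null(priors) && nrow(centers))
    priors <- rep(1 / nrow(centers), nrow(centers))
  if (is.null(priors)) priors <- numeric(0)
  if (nrow(centers) && is.null(rownames(centers)))
    rownames(centers) <- paste0("class", seq_len(nrow(centers)))
  if (length(priors) && is.null(names(priors)))
    names(priors) <- rownames(centers)
  obj <- new("LDAModel", scaling = scaling, centers = centers,
             priors = priors, channels = channels, svd = numeric(0))
  obj
}

#' Project readings and classify with a linear discriminant model
#'
#' Scores are the projections onto the discriminant axes; classification is
#' nearest class mean in discriminant space, adjusted by the log prior.
#'
#' @param model an \code{\link{LDAModel}}.
#' @param x readings: matrix / data.frame with the model's channels as
#'   columns, or an \code{\link{OdorFeatureSet}}.
#' @param type \code{"class"} (default) or \code{"scores"}.
#' @return factor of predicted classes, or the score matrix.
#' @export
ldaPredict <- function(model, x, type = c("class", "scores")) {
  type <- match.arg(type)
  stopifnot(is(model, "LDAModel"))
  m <- .featureMatrix(x)
  if (is.null(colnames(m)) && ncol(m) == length(model@channels))
    colnames(m) <- model@channels
  if (!all(model@channels %in% colnames(m)))
    .stopf("model channels (%s) not all present in the table",
           paste(model@channels, collapse = ", "))
  m <- m[, model@channels, drop = FALSE]
  scores <- m %*% model@scaling
  if (type == "scores") return(scores)
  if (!nrow(model@centers))
    .stopf("model has no class centers; only type='scores' is available")
  zc <- model@centers[, model@channels, drop = FALSE] %*% model@scaling
  disc <- vapply(seq_len(nrow(zc)), function(j)
    -0.5 * colSums((t(scores) - zc[j, ])^2) + log(model@priors[[j]]),
    numeric(nrow(scores)))
  disc <- matrix(disc, nrow = nrow(scores))
  factor(rownames(zc)[max.col(disc, ties.method = "first")],
         levels = rownames(zc))
}

#' Confusion matrix (predicted-by-true orientation)
#'
#' Counts with rows = predicted class and columns = true class; per-class
#' accuracy is the diagonal count over the column (true-class) total, in
#' percent. Classes absent from the test truth keep their row (with zero
#' column total and undefined accuracy).
#'
#' @param true,pred class labels of equal length.
#' @param levels class levels ordering the matrix; default: union of both
#'   label sets.
#' @return An \code{\link{OdorConfusion}}.
#' @examples
#' classConfusion(c("a", "a", "b"), c("a", "b", "b"))
#' @export
classConfusion <- function(true, pred, levels = NULL) {
  if (length(true) != length(pred))
    .stopf("'true' and 'pred' must have equal length")
  if (is.null(levels))
    levels <- union(base::levels(factor(pred)), base::levels(factor(true)))
  tt <- factor(true, levels = levels)
  pp <- factor(pred, levels = levels)
  counts <- unclass(table(predicted = pp, true = tt))
  acc <- 100 * diag(counts) / colSums(counts)
  acc[!is.finite(acc)] <- NA_real_
  names(acc) <- levels
  new("OdorConfusion", counts = counts, accuracy = acc)
}
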