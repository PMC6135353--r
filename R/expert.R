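#' Aggregate an expert panel into per-class suitability scores
#'
#' Summarises non-missing suitability ratings per land-cover class: number
#' of responses, min, max, standard deviation in the population
#' (divide-by-n) form, mean suitability, and mean density estimate. Classes
#' without any response are dropped with a warning.
#'
#' @param ratings An `expert_ratings` data frame.
#' @return A `suitability_table` data frame, one row per retained class.
#' @export
aggregate_ratings <- function(ratings) {
  stopifnot(is.data.frame(ratings))
  if (all(is.na(ratings$suitability))) {
    stop("rating set contains no non-missing suitability values",
         call. = FALSE)
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- do.call(rbind, lapply(split(ratings, ratings$class_code), function(d) {
    s <- d$suitability[!is.na(d$suitability)]
    if (!length(s)) return(NULL)
    dens <- d$density_per_100km2[!is.na(d$density_per_100km2)]
    data.frame(class_code = d$class_code[1L], n_responses = length(s),
               min = min(s), max = max(s), sd = pop_sd(s),
               mean_suitability = mean(s),
               mean_density = if (length(dens)) mean(dens) else NA_real_)
  }))
  dropped <- setdiff(unique(ratings$class_code), out$class_code)
  if (length(dropped)) {
    warning("classes with zero responses excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  rownames(out) <- NULL
  out <- out[order(out$class_code), ]
  class(out) <- c("suitability_table", "data.frame")
  out
}

#' Two-way mixed, consistency intraclass correlation (single and averaged)
#'
#' Shrout-Fleiss ICC(3,1) and ICC(3,k) from the two-way ANOVA decomposition
#' of a rater-by-target table, with targets (rows of the ANOVA) being the
#' rated land-cover classes: `ICC(3,1) = (MSR - MSE) / (MSR + (k-1) MSE)`
#' and `ICC(3,k) = (MSR - MSE) / MSR`, where MSR is the between-class and
#' MSE the residual mean square and k the number of raters.
#'
#' @param mat Numeric matrix, experts in rows, classes in columns; `NA` for
#'   missing ratings.
#' @param handling `"complete_case"` (default) drops experts with any
#'   missing class before the ANOVA; `"pairwise"` keeps all non-missing
#'   responses and uses the unbalanced two-way ANOVA with k taken as the
#'   mean number of raters per class.
#' @return A list with `icc_single`, `icc_average`, `n_experts`,
#'   `n_classes`.
#' @export
icc_two_way_mixed <- function(mat, handling = c("complete_case", "pairwise")) {
  handling <- match.arg(handling)
  stopifnot(is.matrix(mat))
  if (handling == "complete_case") {
    keep <- stats::complete.cases(mat)
    mat <- mat[keep, , drop = FALSE]
    if (nrow(mat) < 2L) {
      stop("fewer than 2 complete experts under complete_case handling",
           call. = FALSE)
    }
  }
  keep_cl <- colSums(!is.na(mat)) > 0L
  mat <- mat[, keep_cl, drop = FALSE]
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    stop("need >= 2 experts and >= 2 classes after missingness handling",
         call. = FALSE)
  }
  long <- data.frame(
    rating = as.vector(mat),
    expert = factor(rep(seq_len(nrow(mat)), times = ncol(mat))),
    class = factor(rep(seq_len(ncol(mat)), each = nrow(mat)))
  )
  long <- long[!is.na(long$rating), ]
  fit <- stats::aov(rating ~ class + expert, data = long)
  tab <- summary(fit)[[1L]]
  msr <- tab["class", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  if (!is.finite(msr) || tab["class", "Sum Sq"] <= .Machine$double.eps^0.5) {
    stop("between-class variance is zero; ICC undefined", call. = FALSE)
  }
  k <- if (handling == "complete_case") nrow(mat) else
    mean(colSums(!is.na(mat)))
  list(icc_single = (msr - mse) / (msr + (k - 1) * mse),
       icc_average = (msr - mse) / msr,
       n_experts = nrow(mat), n_classes = ncol(mat))
}

#' Ratings matrix (experts x classes) from a long rating set
#'
#' @param ratings An `expert_ratings` data frame.
#' @return A numeric matrix with one row per expert, one column per class.
#' @export
ratings_matrix <- function(ratings) {
  experts <- sort(unique(ratings$expert_id))
  classes <- sort(unique(ratings$class_code))
  m <- matrix(NA_real_, length(experts), length(classes),
              dimnames = list(experts, classes))
  m[cbind(match(ratings$expert_id, experts),
          match(ratings$class_code, classes))] <- ratings$suitability
  m
}

#' Coefficient of determination of mean density on mean suitability
#'
#' Ordinary least squares of the per-class mean density estimate on the
#' per-class mean suitability score; quantifies the internal consistency of
#' the panel's two elicited quantities.
#'
#' @param table A `suitability_table`.
#' @return R-squared in \[0, 1\].
#' @export
suitability_density_fit <- function(table) {
  d <- table[!is.na(table$mean_suitability) & !is.na(table$mean_density), ]
  if (nrow(d) < 3L) {
    stop("need >= 3 classes with both mean suitability and density",
         call. = FALSE)
  }
  if (stats::var(d$mean_suitability) == 0) {
    stop("zero variance in mean suitability; fit undefined", call. = FALSE)
  }
  # constant density: nothing to explain, R^2 is 0 by definition
  if (stats::var(d$mean_density) == 0) return(0)
  fit <- stats::lm(mean_density ~ mean_suitability, data = d)
  summary(fit)$r.squared
}

#' Panel agreement report
#'
#' Convenience wrapper computing the ICC pair and the suitability-density
#' R-squared for one panel.
#'
#' @param ratings An `expert_ratings` data frame.
#' @param handling Missingness handling for [icc_two_way_mixed()]; the
#'   default here is `"pairwise"` because under realistic per-class
#'   missingness few experts rate every class and complete-case ICC
#'   degenerates.
#' @return A list: `icc_single`, `icc_average`, `r2_density`, `n_complete`.
#' @export
agreement_report <- function(ratings, handling = "pairwise") {
  m <- ratings_matrix(ratings)
  icc <- icc_two_way_mixed(m, handling = handling)
  tab <- aggregate_ratings(ratings)
  list(icc_single = icc$icc_single, icc_average = icc$icc_average,
       r2_density = suitability_density_fit(tab),
       n_complete = sum(stats::complete.cases(m)))
}
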