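# Bootstrap comparison of functional-category (COG-letter) profiles between
# two genomes, XIPE-style: equal-size subsamples are drawn repeatedly from
# each profile's empirical category distribution, and per-category
# differences in proportion are summarized by their median and an
# equal-tailed percentile interval.

#' Build a functional-category profile
#'
#' @param name Genome label.
#' @param counts Named numeric vector: category letter -> gene count.  Genes
#'   annotated with several letters should contribute one count per letter.
#' @return A list of class `CategoryProfile`.
#' @export
category_profile <- function(name, counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0 || any(counts < 0)) stop("counts must be positive")
  structure(list(name = name, counts = counts, total = sum(counts)),
            class = "CategoryProfile")
}

#' Category profile of an annotated genome
#'
#' Tabulates the single-letter `category` annotations of a
#' [genome_record()]; genes carrying several letters contribute one count
#' per letter.
#'
#' @param g A [genome_record()].
#' @return A [category_profile()].
#' @export
genome_category_profile <- function(g) {
  cats <- g$features$category
  cats <- cats[!is.na(cats) & nzchar(cats)]
  letters <- unlist(strsplit(cats, ""))
  category_profile(g$name, table(letters))
}

#' Bootstrap comparison of two category profiles
#'
#' Per replicate, `subsample` category labels are drawn (with replacement by
#' default) from each profile's empirical distribution; the per-category
#' difference in proportion (a minus b) is recorded.  Each category is
#' summarized by the median difference and the equal-tailed percentile
#' interval at confidence `conf`; it is called significant when the interval
#' excludes zero.
#'
#' @param a,b [category_profile()]s.
#' @param subsample Labels drawn per replicate from each profile.
#' @param n_boot Number of bootstrap replicates.
#' @param conf Confidence level of the equal-tailed interval.
#' @param seed Random seed (mandatory, for reproducibility).
#' @param replace Draw with replacement (bootstrap proper).  With
#'   `replace = FALSE`, `subsample` must not exceed either profile total.
#' @return A list of class `CategoryComparison` with a data.frame `table`
#'   (`category`, `median_diff`, `ci_low`, `ci_high`, `significant`) and the
#'   call parameters.
#' @export
bootstrap_compare <- function(a, b, subsample = 4000, n_boot = 10000,
                              conf = 0.98, seed, replace = TRUE) {
  stopifnot(inherits(a, "CategoryProfile"), inherits(b, "CategoryProfile"))
  if (missing(seed)) stop("seed is mandatory")
  if (a$total < subsample || b$total < subsample) {
    if (!replace) stop("subsample exceeds a profile total and replace = FALSE")
    warning("subsample exceeds a profile total; sampling is with replacement")
  }
  cats <- sort(union(names(a$counts), names(b$counts)))
  pa <- stats::setNames(numeric(length(cats)), cats)
  pb <- pa
  pa[names(a$counts)] <- a$counts / a$total
  pb[names(b$counts)] <- b$counts / b$total
  # each profile gets its own substream keyed by (seed, profile name) so the
  # comparison is exactly antisymmetric under argument swap
  nm_a <- a$name; nm_b <- b$name
  if (identical(nm_a, nm_b)) { nm_a <- paste0(nm_a, "/1"); nm_b <- paste0(nm_b, "/2") }
  sub_seed <- function(name) {
    u <- utf8ToInt(name)
    (abs(seed) * 131L + sum(u * seq_along(u))) %% 2147483647L
  }
  draw <- function(p, counts, total, name) {
    set.seed(sub_seed(name))
    if (replace) {
      # multinomial draw == sampling labels with replacement
      stats::rmultinom(n_boot, subsample, p) / subsample
    } else {
      labs <- rep(names(counts), counts)
      q <- vapply(seq_len(n_boot), function(i) {
        tab <- table(factor(sample(labs, subsample, replace = FALSE), levels = cats))
        as.numeric(tab) / subsample
      }, numeric(length(cats)))
      rownames(q) <- cats
      q
    }
  }
  qa <- draw(pa, a$counts, a$total, nm_a)
  qb <- draw(pb, b$counts, b$total, nm_b)
  diffs <- qa - qb
  alpha <- (1 - conf) / 2
  tab <- data.frame(
    category = cats,
    median_diff = apply(diffs, 1, stats::median),
    ci_low = apply(diffs, 1, stats::quantile, probs = alpha),
    ci_high = apply(diffs, 1, stats::quantile, probs = 1 - alpha),
    stringsAsFactors = FALSE)
  tab$significant <- tab$ci_low > 0 | tab$ci_high < 0
  rownames(tab) <- NULL
  structure(list(table = tab, subsample = subsample, n_boot = n_boot,
                 conf = conf, seed = seed, replace = replace,
                 names = c(a$name, b$name)),
            class = "CategoryComparison")
}

#' @export
print.CategoryComparison <- function(x, ...) {
  cat(sprintf("Category comparison %s vs %s (%d x %d bootstrap, %.0f%% interval)\n",
              x$names[1], x$names[2], x$n_boot, x$subsample, 100 * x$conf))
  sig <- x$table[x$table$significant, , drop = FALSE]
  if (nrow(sig) == 0) cat("no significant categories\n") else {
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  %s: median diff %+0.4f [%+0.4f, %+0.4f]\n",
                  sig$category[i], sig$median_diff[i], sig$ci_low[i], sig$ci_high[i]))
    }
  }
  invisible(x)
}
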