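#' LMG relative-importance decomposition of explained variance
#'
#' Partitions the R-squared of a linear model among groups of predictors by
#' the LMG metric: each group's share is the average, over orderings in
#' which the groups can enter the model, of the increase in R-squared when
#' the group is added.  With `marginality = TRUE`, only orderings in which
#' every interaction group enters after all of its parent main-effect
#' groups are admissible; an interaction can then never be credited with
#' variance attributable to its parents.
#'
#' Two independent computational routes are provided: explicit enumeration
#' of the admissible orderings (`"exact_permutations"`, the default for up
#' to 6 groups), and a subset-weighting formula in which the weight of each
#' predictor subset is the fraction of admissible orderings placing exactly
#' that subset first (`"shapley_subsets"`, computed with a dynamic program
#' over downsets of the parenthood order; no orderings are materialised).
#' Both give identical shares; the two routes cross-check each other.
#'
#' @param response Numeric response vector.
#' @param groups Named list; each element is a numeric vector or matrix of
#'   predictor columns forming one group (e.g. the dummy columns of a
#'   factor, or the product column(s) of an interaction).
#' @param parents Named list mapping a group name to the character vector
#'   of its parent group names; groups absent from `parents` have none.
#'   Ignored when `marginality = FALSE`.
#' @param marginality Restrict orderings so interactions follow their
#'   parents (default `TRUE`).
#' @param method `"exact_permutations"` or `"shapley_subsets"`; the default
#'   picks enumeration for <= 6 groups and the subset formula above that.
#' @return A list of class `variance_partition`: `shares` (named, on the
#'   R-squared scale, summing to `r2_full`), `shares_pct_total` (percent of
#'   total response variance), `shares_pct_explained` (percent of explained
#'   variance), `r2_full`, `method`, `n`.
#' @examples
#' set.seed(1)
#' x1 <- rnorm(50); x2 <- rnorm(50)
#' y <- x1 + 0.5 * x2 + rnorm(50)
#' lmg_shares(y, list(x1 = x1, x2 = x2))
#' @export
lmg_shares <- function(response, groups, parents = NULL,
                       marginality = TRUE,
                       method = c("auto", "exact_permutations",
                                  "shapley_subsets")) {
  method <- match.arg(method)
  p <- length(groups)
  if (p < 1) stop("need at least one predictor group", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("`groups` must be a fully named list", call. = FALSE)
  }
  if (method == "auto") {
    method <- if (p <= 6) "exact_permutations" else "shapley_subsets"
  }
  if (p > 12) stop("more than 12 predictor groups is not supported",
                   call. = FALSE)
  if (method == "exact_permutations" && p > 8) {
    stop("permutation enumeration is limited to 8 groups; use ",
         "`method = \"shapley_subsets\"`", call. = FALSE)
  }
  y <- as.numeric(response)
  mats <- lapply(groups, function(g) {
    m <- as.matrix(g)
    if (nrow(m) != length(y)) {
      stop("group rows must match the response length", call. = FALSE)
    }
    m
  })
  parent_idx <- integer_parent_sets(names(groups), parents, marginality)

  # R2 of every subset of groups, indexed by bitmask
  r2 <- numeric(2^p)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("response has zero variance", call. = FALSE)
  for (s in seq_len(2^p - 1)) {
    members <- which(bitwAnd(s, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    x <- do.call(cbind, c(list(rep(1, length(y))), mats[members]))
    fit <- stats::lm.fit(x, y)
    if (s == 2^p - 1 && fit$rank < ncol(x)) {
      stop("rank-deficient full model", call. = FALSE)
    }
    r2[s + 1L] <- 1 - sum(fit$residuals^2) / tss
  }
  r2_full <- r2[2^p]

  shares <- switch(method,
    exact_permutations = lmg_by_permutations(p, r2, parent_idx),
    shapley_subsets = lmg_by_subsets(p, r2, parent_idx)
  )
  names(shares) <- names(groups)
  structure(
    list(shares = shares,
         shares_pct_total = 100 * shares,
         shares_pct_explained = 100 * shares / r2_full,
         r2_full = r2_full, method = method, n = length(y)),
    class = "variance_partition"
  )
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("LMG variance partition (", x$method, "), R2 = ",
      round(x$r2_full, 4), "\n", sep = "")
  print(round(x$shares_pct_total, 2))
  invisible(x)
}

integer_parent_sets <- function(nms, parents, marginality) {
  p <- length(nms)
  masks <- integer(p)
  if (!marginality || is.null(parents)) return(masks)
  unknown <- setdiff(names(parents), nms)
  if (length(unknown)) {
    stop("unknown group(s) in `parents`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(parents)) {
    idx <- match(parents[[nm]], nms)
    if (any(is.na(idx))) {
      stop("unknown parent(s) of ", nm, call. = FALSE)
    }
    masks[match(nm, nms)] <- sum(bitwShiftL(1L, idx - 1L))
  }
  masks
}

# ordering admissible iff every element is preceded by its parents
lmg_by_permutations <- function(p, r2, parent_masks) {
  perms <- all_permutations(p)
  shares <- numeric(p)
  n_adm <- 0L
  for (i in seq_len(nrow(perms))) {
    ord <- perms[i, ]
    seen <- 0L
    ok <- TRUE
    inc <- numeric(p)
    for (g in ord) {
      if (bitwAnd(parent_masks[g], seen) != parent_masks[g]) {
        ok <- FALSE
        break
      }
      new_seen <- bitwOr(seen, bitwShiftL(1L, g - 1L))
      inc[g] <- r2[new_seen + 1L] - r2[seen + 1L]
      seen <- new_seen
    }
    if (ok) {
      n_adm <- n_adm + 1L
      shares <- shares + inc
    }
  }
  if (n_adm == 0L) stop("no admissible ordering (cyclic parenthood?)",
                        call. = FALSE)
  shares / n_adm
}

all_permutations <- function(p) {
  if (p == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(p - 1L)
  out <- matrix(0L, nrow(sub) * p, p)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(p)) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], p, after = pos - 1L)
    }
  }
  out
}

# Subset-weight route: weight(S, g) = N(S) * C(S + g) / C(0), where N(S)
# counts admissible orderings of the downset S and C(P) counts admissible
# completions after prefix P.  Both counts satisfy simple recursions over
# downsets and are memoised over bitmasks.
lmg_by_subsets <- function(p, r2, parent_masks) {
  full <- 2^p - 1L
  bit <- bitwShiftL(1L, seq_len(p) - 1L)

  n_prefix <- rep(NA_real_, 2^p)   # N(S)
  n_prefix[1] <- 1
  count_prefix <- function(s) {
    if (!is.na(n_prefix[s + 1L])) return(n_prefix[s + 1L])
    total <- 0
    for (g in seq_len(p)) {
      if (bitwAnd(s, bit[g]) == 0L) next
      rest <- bitwAnd(s, bitwNot(bit[g]))
      # g can come last in S iff its parents are all in rest
      if (bitwAnd(parent_masks[g], rest) == parent_masks[g]) {
        total <- total + count_prefix(rest)
      }
    }
    n_prefix[s + 1L] <<- total
    total
  }

  n_suffix <- rep(NA_real_, 2^p)   # C(P)
  n_suffix[full + 1L] <- 1
  count_suffix <- function(s) {
    if (!is.na(n_suffix[s + 1L])) return(n_suffix[s + 1L])
    total <- 0
    for (g in seq_len(p)) {
      if (bitwAnd(s, bit[g]) != 0L) next
      if (bitwAnd(parent_masks[g], s) == parent_masks[g]) {
        total <- total + count_suffix(bitwOr(s, bit[g]))
      }
    }
    n_suffix[s + 1L] <<- total
    total
  }

  n_total <- count_suffix(0L)
  if (n_total == 0) stop("no admissible ordering (cyclic parenthood?)",
                         call. = FALSE)
  shares <- numeric(p)
  for (g in seq_len(p)) {
    others <- bitwAnd(full, bitwNot(bit[g]))
    for (s in 0:full) {
      if (bitwAnd(s, others) != s) next              # not a subset of others
      if (bitwAnd(parent_masks[g], s) != parent_masks[g]) next
      np <- count_prefix(s)
      if (np > 0) {
        w <- np * count_suffix(bitwOr(s, bit[g])) / n_total
        shares[g] <- shares[g] +
          w * (r2[bitwOr(s, bit[g]) + 1L] - r2[s + 1L])
      }
    }
  }
  shares
}

#' LMG partition of SMR variance among mass, temperature and site
#'
#' Convenience wrapper assembling the predictor groups of the global SMR
#' model — `ln M`, temperature (degrees C, continuous), collection site
#' (dummy-coded) and the `ln M x T` interaction (with `ln M` and `T` as its
#' parents) — and calling [lmg_shares()] on `ln SMR`.
#'
#' @param records Metabolic records.
#' @param include_interaction Include the mass x temperature interaction
#'   group (default `TRUE`).
#' @param method Passed to [lmg_shares()].
#' @return A `variance_partition` (see [lmg_shares()]).
#' @export
smr_variance_partition <- function(records, include_interaction = TRUE,
                                   method = "auto") {
  df <- as.data.frame(records)
  stopifnot(all(c("dry_mass_mg", "smr_j_per_day", "temp_level_c", "site")
                %in% names(df)))
  ln_m <- log(df$dry_mass_mg)
  t_c <- df$temp_level_c
  y <- log(df$smr_j_per_day)
  groups <- list(lnM = ln_m, T = t_c)
  parents <- NULL
  site <- factor(df$site)
  if (nlevels(site) > 1) {
    groups$site <- stats::model.matrix(~ site)[, -1, drop = FALSE]
  }
  if (include_interaction) {
    # centre before multiplying so the product is not collinear shorthand
    # for its parents
    groups$`lnM:T` <- (ln_m - mean(ln_m)) * (t_c - mean(t_c))
    parents <- list(`lnM:T` = c("lnM", "T"))
  }
  lmg_shares(y, groups, parents = parents, method = method)
}

#' One-way analysis of variance
#'
#' Classical one-way ANOVA of a numeric response across groups (wraps
#' [stats::aov()]), used e.g. to compare body mass or SMR among collection
#' sites.
#'
#' @param values Numeric response.
#' @param groups Grouping vector (coerced to factor), >= 2 levels with
#'   >= 2 values each.
#' @return A list with `f`, `df1`, `df2`, `p` and the `aov` `table`.
#' @examples
#' anova_oneway(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
#' @export
anova_oneway <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  fit <- aov(values ~ g)
  tab <- summary(fit)[[1]]
  list(f = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
       p = tab$`Pr(>F)`[1], table = tab)
}
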