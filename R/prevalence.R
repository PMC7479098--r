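# Prevalence/abundance layer: per-sample relative abundance, prevalence with
# 5%-bin histogram, low/medium/high stratification, per-individual summaries
# and physiological role annotation.

#' Per-sample relative abundance (percent)
#'
#' Rescales each sample column of a count table to sum to 100:
#' `(SLP reads / total reads) x 100` per sample.
#'
#' @param table non-negative matrix, rows = SLPs, columns = samples.
#' @return matrix of percentages; every column sums to 100.
#' @export
relative_abundance <- function(table) {
  cs <- colSums(table)
  if (any(cs == 0))
    stop("sample(s) with zero total reads: ",
         paste(colnames(table)[cs == 0], collapse = ", "))
  sweep(table, 2, cs, "/") * 100
}

#' SLP prevalence and 5%-interval histogram
#'
#' Prevalence of an SLP is the percentage of samples where its count exceeds
#' `min_count - 1` (presence = count > 0 by default). The histogram bins
#' prevalence into 5% intervals `[0,5), [5,10), ..., [95,100]`.
#'
#' @param table count matrix, rows = SLPs, columns = samples (>= 1).
#' @param min_count minimal count that scores presence (default 1).
#' @return list with `prevalence` (named percent vector) and `histogram`
#'   (data.frame: bin label, n_slps, mean_relative_abundance of member SLPs,
#'   percent of pooled reads).
#' @export
prevalence <- function(table, min_count = 1) {
  if (ncol(table) < 1) stop("need at least one sample")
  pres <- table >= min_count
  prev <- 100 * rowSums(pres) / ncol(table)
  breaks <- seq(0, 100, by = 5)
  bin <- cut(prev, breaks = breaks, right = FALSE, include.lowest = FALSE,
             labels = sprintf("[%d,%d)", breaks[-21], breaks[-1]))
  bin[prev == 100] <- "[95,100)"
  bin[prev == 0] <- "[0,5)"
  ra <- relative_abundance(table)
  hist <- data.frame(
    bin = levels(bin),
    n_slps = as.integer(table(bin)),
    mean_relative_abundance = vapply(levels(bin), function(b) {
      i <- which(bin == b)
      if (length(i) == 0) return(0)
      mean(rowMeans(ra[i, , drop = FALSE]))
    }, 0),
    pooled_read_percent = vapply(levels(bin), function(b) {
      i <- which(bin == b)
      100 * sum(table[i, , drop = FALSE]) / sum(table)
    }, 0),
    stringsAsFactors = FALSE)
  list(prevalence = prev, histogram = hist)
}

#' Stratify SLPs into prevalence groups
#'
#' Low: prevalence < 10%; medium: 10% <= prevalence <= 60% (the 60% boundary
#' is medium); high: prevalence > 60%.
#'
#' @param prev prevalence percentages in `[0, 100]`.
#' @return character vector of group labels.
#' @export
stratify <- function(prev) {
  if (any(prev < 0 | prev > 100)) stop("prevalence must be in [0, 100]")
  ifelse(prev < 10, "low", ifelse(prev <= 60, "medium", "high"))
}

#' Per-sample SLP carriage summary
#'
#' For each sample: total SLPs detected, SLP counts per prevalence group, and
#' counts plus summed relative abundance per physiological role.
#'
#' @param table count matrix (SLPs x samples).
#' @param groups named prevalence-group labels per SLP (from [stratify()]).
#' @param roles optional named role vector keyed by SLP id (species-name
#'   matched roles: probiotic / commensal / potential_pathogen); SLPs without
#'   a role are `unassigned`. Unknown names draw a warning, not an error.
#' @param min_count presence floor, as in [prevalence()].
#' @return data.frame, one row per sample.
#' @export
per_sample_summary <- function(table, groups, roles = NULL, min_count = 1) {
  slps <- rownames(table)
  if (!all(slps %in% names(groups))) stop("groups must cover every SLP")
  if (!is.null(roles) && length(setdiff(names(roles), slps)) > 0)
    warning("role list names unknown SLPs: ",
            paste(setdiff(names(roles), slps), collapse = ", "))
  role_of <- setNames(rep("unassigned", length(slps)), slps)
  if (!is.null(roles)) {
    known <- intersect(names(roles), slps)
    role_of[known] <- roles[known]
  }
  ra <- relative_abundance(table)
  pres <- table >= min_count
  g <- groups[slps]
  out <- lapply(colnames(table), function(s) {
    p <- pres[, s]
    data.frame(
      sample_id = s,
      n_slps = sum(p),
      n_low = sum(p & g == "low"),
      n_medium = sum(p & g == "medium"),
      n_high = sum(p & g == "high"),
      n_probiotic = sum(p & role_of == "probiotic"),
      n_commensal = sum(p & role_of == "commensal"),
      n_potential_pathogen = sum(p & role_of == "potential_pathogen"),
      ra_probiotic = sum(ra[p & role_of == "probiotic", s]),
      ra_commensal = sum(ra[p & role_of == "commensal", s]),
      ra_potential_pathogen = sum(ra[p & role_of == "potential_pathogen", s]),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pooled and mean relative abundance per prevalence group
#'
#' Both readings of a group's share are returned: percent of all reads pooled
#' across samples, and the mean of per-sample percentages.
#'
#' @param table count matrix.
#' @param groups named group labels per SLP.
#' @return data.frame: group, n_slps, pooled_read_percent,
#'   mean_sample_percent.
#' @export
group_abundance <- function(table, groups) {
  ra <- relative_abundance(table)
  g <- groups[rownames(table)]
  out <- lapply(c("low", "medium", "high"), function(lv) {
    i <- which(g == lv)
    data.frame(group = lv, n_slps = length(i),
               pooled_read_percent = 100 * sum(table[i, , drop = FALSE]) / sum(table),
               mean_sample_percent = mean(colSums(ra[i, , drop = FALSE])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
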