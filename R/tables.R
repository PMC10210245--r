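# Bookkeeping on weight tables: class totals, branching ratios,
# dominant-trajectory counts. Two example best-fit tables ship with the
# package (CHD ring-opening probed by ultrafast X-ray scattering; CS2
# photodissociation probed by ultrafast electron diffraction).

#' Example best-fit weight tables
#'
#' Dominant-trajectory weight tables from published forward-optimization
#' fits of two photochemical systems: the electrocyclic ring-opening of
#' 1,3-cyclohexadiene (labels `open`/`closed`, UXS probe) and the
#' photodissociation of CS2 (labels `singlet`/`triplet`/`bound`, UED
#' probe). Weights are percentages of the total model weight.
#'
#' @param system `"chd"` or `"cs2"`.
#' @return Data frame with columns `trajectory_id`, `label`,
#'   `weight_pct`.
#' @export
example_weight_table <- function(system = c("chd", "cs2")) {
  system <- match.arg(system)
  path <- system.file("extdata", paste0(system, "_weights.tsv"),
                      package = "tbfit", mustWork = TRUE)
  read_weight_table(path)
}

#' Read a weight table
#'
#' @param path Tab-delimited file with columns `trajectory_id`, `label`
#'   and either `weight_pct` (percent) or `weight` (fraction).
#' @return Data frame with both `weight_pct` and `weight` columns.
#' @export
read_weight_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"weight_pct" %in% names(df) && "weight" %in% names(df))
    df$weight_pct <- 100 * df$weight
  if (!all(c("trajectory_id", "label", "weight_pct") %in% names(df)))
    stop("weight table needs trajectory_id, label and weight(_pct) columns",
         call. = FALSE)
  df$weight <- df$weight_pct / 100
  df
}

#' Write a weight table
#'
#' @param df Data frame with `trajectory_id`, `label` and `weight`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(df, path) {
  out <- data.frame(trajectory_id = df$trajectory_id, label = df$label,
                    weight = sprintf("%.17g", df$weight))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Total weight per class
#'
#' Sums weights over trajectories whose label matches each pattern
#' (regular expression, so `"open"` also catches `"open (indirect)"`).
#'
#' @param table Weight table (data frame with `label`, `weight_pct`).
#' @param classes Named character vector of label patterns; defaults to
#'   one class per distinct label.
#' @return Named numeric vector of percentage totals.
#' @export
class_totals <- function(table, classes = NULL) {
  if (is.null(classes)) {
    classes <- unique(table$label)
    names(classes) <- classes
    vapply(classes, function(l)
      sum(table$weight_pct[table$label == l]), numeric(1))
  } else {
    vapply(classes, function(pat)
      sum(table$weight_pct[grepl(pat, table$label)]), numeric(1))
  }
}

#' Branching ratio between two classes
#'
#' @param table Weight table.
#' @param num,den Label patterns for the numerator and denominator class.
#' @return Scalar ratio `total(den) / total(num)`, i.e. the `r` of a
#'   `num : den = 1 : r` branching statement.
#' @export
branching_ratio <- function(table, num, den) {
  tot <- class_totals(table, c(num = num, den = den))
  if (tot[["num"]] == 0) stop("numerator class has zero weight",
                              call. = FALSE)
  tot[["den"]] / tot[["num"]]
}

#' Count dominant trajectories
#'
#' @param table Weight table.
#' @param threshold_pct Weight threshold in percent (default 1%).
#' @return Integer count of trajectories above the threshold.
#' @export
dominant_count <- function(table, threshold_pct = 1) {
  sum(table$weight_pct > threshold_pct)
}
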