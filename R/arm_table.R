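#' @importFrom utils read.csv write.csv
NULL

# Canonical CSV schema (one dialect; empty cell = absent).
.arm_schema <- c("study", "author", "n", "brfs_5y", "total_dose",
                 "n_fractions", "dose_per_fraction", "c", "definition",
                 "risk_group", "subset_of_pooled")

.numeric_cols <- c("n", "brfs_5y", "total_dose", "n_fractions",
                   "dose_per_fraction", "c")

# Relative tolerance for derived-column consistency (0.5%); published tables
# round the quadratic dose column, so exact equality cannot be demanded.
.derived_tol <- 0.005

#' Construct an arm table
#'
#' An arm table is the unit of fitting: a non-empty, ordered collection of
#' published treatment arms from one fractionation group.  It is a
#' `data.frame` with one row per arm and attributes `group_label` and
#' `regimen`.  Row order is stable: jackknife replicate indices refer to it.
#'
#' @param arms `data.frame` with columns `study`, `author`, `n`, `brfs_5y`,
#'   `total_dose`, `n_fractions`, `dose_per_fraction`, `c`, `definition`,
#'   `risk_group`, `subset_of_pooled`.  `n_fractions` or `dose_per_fraction`
#'   may be `NA` arm-wise (not both); `c` is filled from the dose schedule
#'   when absent.
#' @param group_label Character label for the group.
#' @param regimen One of `"conventional"`, `"moderate_hypo"`, `"sbrt"`,
#'   `"mixed"`.
#' @return An object of class `arm_table`.
#' @seealso [read_arm_table()], [load_fixture()], [validate_arm_table()]
#' @export
arm_table <- function(arms, group_label = "table",
                      regimen = c("mixed", "conventional", "moderate_hypo", "sbrt")) {
  regimen <- match.arg(regimen)
  arms <- as.data.frame(arms, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.arm_schema, names(arms))
  for (col in missing_cols) {
    arms[[col]] <- if (col == "subset_of_pooled") FALSE else NA
  }
  arms <- arms[.arm_schema]
  for (col in .numeric_cols) arms[[col]] <- as.numeric(arms[[col]])
  arms$study <- as.character(arms$study)
  arms$author <- as.character(arms$author)
  arms$definition <- .normalize_definition(arms$definition)
  arms$risk_group <- as.character(arms$risk_group)
  sp <- arms$subset_of_pooled
  arms$subset_of_pooled <- !is.na(sp) & (sp == TRUE | tolower(as.character(sp)) == "true")

  # fill derived fields: d from D and N, then C from D and d (or D^2/N)
  fill_d <- is.na(arms$dose_per_fraction) & !is.na(arms$n_fractions)
  arms$dose_per_fraction[fill_d] <-
    arms$total_dose[fill_d] / arms$n_fractions[fill_d]
  fill_c <- is.na(arms$c)
  arms$c[fill_c] <- ifelse(!is.na(arms$n_fractions[fill_c]),
                           arms$total_dose[fill_c]^2 / arms$n_fractions[fill_c],
                           arms$total_dose[fill_c] * arms$dose_per_fraction[fill_c])

  out <- structure(arms,
                   class = c("arm_table", "data.frame"),
                   group_label = group_label,
                   regimen = regimen)
  .assert_arm_invariants(out)
  out
}

.normalize_definition <- function(x) {
  x <- as.character(x)
  x[x %in% c("P", "p", "Phoenix", "phoenix")] <- "Phoenix"
  x[x %in% c("A", "a", "ASTRO", "astro")] <- "ASTRO"
  bad <- !is.na(x) & !(x %in% c("Phoenix", "ASTRO"))
  if (any(bad)) {
    stop("unknown bRFS definition: ", paste(unique(x[bad]), collapse = ", "),
         " (expected Phoenix or ASTRO)", call. = FALSE)
  }
  x
}

.assert_arm_invariants <- function(tab) {
  if (nrow(tab) == 0L) stop("arm table must be non-empty", call. = FALSE)
  problems <- character(0)
  bad_row <- function(i, msg) sprintf("arm %d (%s): %s", i, tab$author[i], msg)
  for (i in seq_len(nrow(tab))) {
    n <- tab$n[i]; p <- tab$brfs_5y[i]; D <- tab$total_dose[i]
    N <- tab$n_fractions[i]; d <- tab$dose_per_fraction[i]; C <- tab$c[i]
    if (is.na(n) || n < 1 || n != round(n))
      problems <- c(problems, bad_row(i, "n_patients must be a positive integer"))
    if (is.na(p) || p < 0 || p > 1)
      problems <- c(problems, bad_row(i, "brfs_5y must lie in [0, 1]"))
    if (is.na(D) || D <= 0)
      problems <- c(problems, bad_row(i, "total_dose must be positive"))
    if (is.na(N) && is.na(d))
      problems <- c(problems, bad_row(i, "need n_fractions or dose_per_fraction"))
    if (!is.na(N) && !is.na(d) && abs(D - N * d) > .derived_tol * D)
      problems <- c(problems, bad_row(i, sprintf(
        "total_dose %.4g inconsistent with n_fractions * dose_per_fraction = %.4g",
        D, N * d)))
    C_ref <- if (!is.na(N)) D^2 / N else D * d
    if (!is.na(C) && abs(C - C_ref) > .derived_tol * C)
      problems <- c(problems, bad_row(i, sprintf(
        "quadratic dose c = %.6g disagrees with D^2/N (or D*d) = %.6g", C, C_ref)))
  }
  if (length(problems)) {
    stop("invalid arm table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(tab)
}

#' @export
print.arm_table <- function(x, ...) {
  cat(sprintf("Arm table '%s' (%s regimen): %d arms, %d patients\n",
              attr(x, "group_label"), attr(x, "regimen"),
              nrow(x), sum(x$n)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' @export
`[.arm_table` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(.arm_schema %in% names(out))) {
    attr(out, "group_label") <- attr(x, "group_label")
    attr(out, "regimen") <- attr(x, "regimen")
    class(out) <- c("arm_table", "data.frame")
  }
  out
}

#' Read an arm table from CSV
#'
#' Reads the canonical comma-separated schema
#' `study,author,n,brfs_5y,total_dose,n_fractions,dose_per_fraction,c,definition,risk_group,subset_of_pooled`
#' (UTF-8, mandatory header, empty cell = absent value).  Derived fields are
#' filled from the dose schedule: the dose per fraction from `D/N`, and the
#' quadratic dose `c` from `D^2/N` (or `D*d` when only the fraction size is
#' given).
#'
#' @param path Path to a CSV file.
#' @param group_label Label for the resulting table (defaults to the file
#'   name without extension).
#' @param regimen Regimen label, as in [arm_table()].
#' @return An [arm_table()].
#' @export
read_arm_table <- function(path, group_label = NULL, regimen = "mixed") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(group_label)) group_label <- sub("\\.[^.]*$", "", basename(path))
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = "")
  missing_cols <- setdiff(.arm_schema, names(raw))
  if (length(missing_cols)) {
    stop("CSV schema error in ", basename(path), ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in .numeric_cols) {
    vals <- raw[[col]]
    conv <- suppressWarnings(as.numeric(vals))
    bad <- !is.na(vals) & is.na(conv)
    if (any(bad)) {
      stop(sprintf("parse error in %s, column '%s', row %d: '%s' is not numeric",
                   basename(path), col, which(bad)[1], vals[which(bad)[1]]),
           call. = FALSE)
    }
    raw[[col]] <- conv
  }
  arm_table(raw, group_label = group_label, regimen = regimen)
}

#' Write an arm table to CSV
#'
#' Inverse of [read_arm_table()]: numeric fields are written as plain decimal
#' strings (no scientific notation) so that a read/write round trip
#' reproduces them exactly.
#'
#' @param table An [arm_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_arm_table <- function(table, path) {
  stopifnot(inherits(table, "arm_table"))
  out <- as.data.frame(table)
  # a dose per fraction that is exactly D/N was derived at read time; write
  # it as absent so a re-read re-derives the identical value
  derived_d <- !is.na(out$n_fractions) &
    out$dose_per_fraction == out$total_dose / out$n_fractions
  out$dose_per_fraction[derived_d] <- NA_real_
  for (col in .numeric_cols) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         format(out[[col]], digits = 15, scientific = FALSE,
                                trim = TRUE))
  }
  out$subset_of_pooled <- ifelse(out$subset_of_pooled, "true", "")
  out$risk_group[is.na(out$risk_group)] <- ""
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Load a packaged fixture table
#'
#' Returns one of the three transcribed fractionation groups shipped with the
#' package: `"conventional"` (22 arms, 7793 patients), `"moderate_hypo"`
#' (31 arms, 6822 patients) or `"sbrt"` (11 printed arms; 1827 patients when
#' each pooled multi-institution study is counted once).
#'
#' The SBRT table keeps all printed rows; the three risk-subset rows of the
#' pooled 1100-patient study are flagged `subset_of_pooled` and can be
#' dropped with `drop_pooled_subsets = TRUE`.
#'
#' @param name Fixture name.
#' @param drop_pooled_subsets Drop arms flagged as subsets of a pooled row.
#' @return An [arm_table()].
#' @export
load_fixture <- function(name = c("conventional", "moderate_hypo", "sbrt"),
                         drop_pooled_subsets = FALSE) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "lqtcp",
                      mustWork = TRUE)
  tab <- read_arm_table(path, group_label = name, regimen = name)
  if (drop_pooled_subsets) tab <- tab[!tab$subset_of_pooled, ]
  tab
}

#' Classify a fractionation regimen by dose per fraction
#'
#' Interval definitions: conventional 1.8–2.1 Gy per fraction, moderate
#' hypofractionation 2.19–3.5 Gy, SBRT 6.5 Gy or greater.  Fraction sizes in
#' the definitional gaps (e.g. 2.11–2.18 or 3.51–6.49 Gy) are
#' `"unclassified"`.
#'
#' @param dose_per_fraction Numeric vector of fraction sizes in Gy (> 0).
#' @return Character vector: `"conventional"`, `"moderate_hypo"`, `"sbrt"` or
#'   `"unclassified"`.
#' @export
classify_regimen <- function(dose_per_fraction) {
  d <- as.numeric(dose_per_fraction)
  if (any(is.na(d)) || any(d <= 0)) {
    stop("dose_per_fraction must be positive", call. = FALSE)
  }
  out <- rep("unclassified", length(d))
  eps <- 1e-9  # interval edges are decimal doses; guard binary rounding
  out[d >= 1.8 - eps & d <= 2.1 + eps] <- "conventional"
  out[d >= 2.19 - eps & d <= 3.5 + eps] <- "moderate_hypo"
  out[d >= 6.5 - eps] <- "sbrt"
  out
}

#' Validate an arm table and report findings
#'
#' Runs data-quality checks that are warnings rather than hard invariants:
#' derived-column mismatches, disagreement between the table's regimen label
#' and [classify_regimen()] per arm, fully duplicated arms, and suspected
#' pooled-cohort overlap (an arm whose patient count equals the sum of other
#' arms by the same author).
#'
#' @param table An [arm_table()].
#' @return A `data.frame` of findings with columns `severity`, `arm`,
#'   `author`, `message`; zero rows when nothing is flagged.
#' @export
validate_arm_table <- function(table) {
  stopifnot(inherits(table, "arm_table"))
  findings <- list()
  add <- function(severity, arm, author, message) {
    findings[[length(findings) + 1L]] <<-
      data.frame(severity = severity, arm = arm, author = author,
                 message = message, stringsAsFactors = FALSE)
  }
  regimen <- attr(table, "regimen")
  for (i in seq_len(nrow(table))) {
    D <- table$total_dose[i]; N <- table$n_fractions[i]
    d <- table$dose_per_fraction[i]; C <- table$c[i]
    C_ref <- if (!is.na(N)) D^2 / N else D * d
    rel <- abs(C - C_ref) / C
    if (rel > 1e-12 && rel <= .derived_tol) {
      add("note", i, table$author[i], sprintf(
        "stored c = %.6g is a rounded D^2/N = %.6g (relative gap %.2g)",
        C, C_ref, rel))
    }
    if (regimen != "mixed" && !is.na(d)) {
      cls <- classify_regimen(d)
      if (cls != regimen) {
        add("warning", i, table$author[i], sprintf(
          "dose per fraction %.3g Gy classifies as '%s', table labelled '%s'",
          d, cls, regimen))
      }
    }
  }
  key <- paste(table$author, table$n, table$brfs_5y, table$total_dose,
               table$n_fractions, table$dose_per_fraction)
  dup <- duplicated(key)
  for (i in which(dup)) {
    add("warning", i, table$author[i], "duplicate arm (identical label and data)")
  }
  for (a in unique(table$author)) {
    idx <- which(table$author == a)
    if (length(idx) < 2L) next
    for (i in idx) {
      others <- setdiff(idx, i)
      if (length(others) >= 2L && table$n[i] == sum(table$n[others])) {
        add("warning", i, a, sprintf(
          "suspected pooled overlap: n = %d equals the sum of the author's other %d arms",
          table$n[i], length(others)))
      }
    }
  }
  if (!length(findings)) {
    return(data.frame(severity = character(0), arm = integer(0),
                      author = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}
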