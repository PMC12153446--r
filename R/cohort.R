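#' @useDynLib symptomnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor sd quantile qnorm pnorm rnorm runif uniroot setNames
#' @importFrom utils read.table write.csv head
NULL

GAD_ITEMS <- paste0("gad", 1:7)
CESD_ITEMS <- paste0("cesd", 1:10)
ALL_ITEMS <- c(GAD_ITEMS, CESD_ITEMS)

#' Node labels of the anxiety-depression item network
#'
#' The 7 GAD-7 anxiety items followed by the 10 CES-D-10 depression items,
#' in instrument order.
#' @return Character vector of length 17 (`GAD1`..`GAD7`, `CESD1`..`CESD10`).
#' @export
node_labels <- function() c(paste0("GAD", 1:7), paste0("CESD", 1:10))

#' Community membership of the network nodes
#'
#' Communities are fixed by instrument membership: GAD-7 items form the
#' anxiety community, CES-D-10 items the depression community.
#' @param labels Node labels; defaults to [node_labels()].
#' @return Named character vector mapping each label to `"anxiety"` or
#'   `"depression"`.
#' @export
node_communities <- function(labels = node_labels()) {
  setNames(ifelse(grepl("^GAD", labels), "anxiety", "depression"), labels)
}

#' Read a participant roster from delimited text
#'
#' Parses a comma- or tab-delimited file with one row per respondent into a
#' standardized roster data frame. Column names in the file are mapped to the
#' canonical fields through `column_map`. Item responses outside \{0,1,2,3\}
#' (including sentinel codes such as 8/9 and blanks, or non-numeric text)
#' become missing with a warning; the record itself is retained for the
#' screening cascade to judge.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named list or vector mapping canonical keys (`id`, `age`,
#'   `sex`, `residence`, `living`, `gad1`..`gad7`, `cesd1`..`cesd10`) to the
#'   column names used in the file. Keys absent from the map are assumed to
#'   use their canonical name.
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A `participant_roster` data frame with columns `id`, `age`, `sex`,
#'   `residence`, `living`, `gad1`..`gad7`, `cesd1`..`cesd10`.
#' @export
parse_roster <- function(path, column_map = list(), sep = NULL) {
  if (!file.exists(path)) stop("roster file not found: ", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", "", "."), quote = "\"",
                           comment.char = "")
  keys <- c("id", "age", "sex", "residence", "living", ALL_ITEMS)
  cmap <- setNames(keys, keys)
  cmap[names(column_map)] <- unlist(column_map)
  missing_cols <- cmap[!(cmap %in% names(raw))]
  if (length(missing_cols))
    stop("roster is missing mapped column(s): ",
         paste0(names(missing_cols), " -> '", missing_cols, "'", collapse = ", "))

  out <- data.frame(id = raw[[cmap[["id"]]]], stringsAsFactors = FALSE)
  out$age <- suppressWarnings(as.numeric(raw[[cmap[["age"]]]]))
  out$age[!is.na(out$age) & out$age < 0] <- NA_real_
  sex <- tolower(trimws(raw[[cmap[["sex"]]]]))
  sex[!(sex %in% c("male", "female"))] <- NA_character_
  out$sex <- sex
  res <- tolower(trimws(raw[[cmap[["residence"]]]]))
  res[!(res %in% c("city", "town", "rural"))] <- NA_character_
  out$residence <- res
  liv <- suppressWarnings(as.integer(raw[[cmap[["living"]]]]))
  liv[!(liv %in% 1:3)] <- NA_integer_
  out$living <- liv

  n_bad <- 0L
  for (item in ALL_ITEMS) {
    v <- suppressWarnings(as.integer(raw[[cmap[[item]]]]))
    bad <- !is.na(v) & !(v %in% 0:3)
    n_bad <- n_bad + sum(bad)
    v[bad] <- NA_integer_
    out[[item]] <- v
  }
  if (n_bad > 0L)
    warning(n_bad, " out-of-range item code(s) set to missing")
  class(out) <- c("participant_roster", "data.frame")
  out
}

#' Apply the staged exclusion cascade
#'
#' Restricts the roster to respondents coded as living alone, then removes
#' records in three disjoint stages, attributing each exclusion to the first
#' stage that rejects it: (1) missing age or sex, or more than one third of
#' the 17 scale items missing; (2) any missing GAD-7 item among stage-1
#' survivors; (3) any missing CES-D item among stage-2 survivors.
#'
#' @param roster A `participant_roster` data frame (see [parse_roster()]).
#' @param living_alone_code Living-arrangement code selecting the analytic
#'   population (default 2 = living alone). Use `NULL` to skip the filter.
#' @return A list with `retained` (the surviving roster) and `report`, a
#'   `screening_report` with stage counts and excluded ids.
#' @export
apply_exclusions <- function(roster, living_alone_code = 2L) {
  stopifnot(is.data.frame(roster))
  if (!is.null(living_alone_code) && nrow(roster) > 0)
    roster <- roster[!is.na(roster$living) &
                       roster$living == living_alone_code, , drop = FALSE]
  n0 <- nrow(roster)
  if (n0 == 0L) {
    report <- structure(list(
      n_initial = 0L, n_excluded_demographic_or_incomplete = 0L,
      n_excluded_missing_gad = 0L, n_excluded_missing_cesd = 0L,
      n_final = 0L,
      excluded_ids_by_stage = list(stage1 = character(0),
                                   stage2 = character(0),
                                   stage3 = character(0))),
      class = "screening_report")
    return(list(retained = roster, report = report))
  }
  items <- as.matrix(roster[, ALL_ITEMS, drop = FALSE])
  n_miss_items <- rowSums(is.na(items))
  stage1 <- is.na(roster$age) | is.na(roster$sex) |
    n_miss_items > length(ALL_ITEMS) / 3
  gad_miss <- rowSums(is.na(roster[, GAD_ITEMS, drop = FALSE])) > 0
  cesd_miss <- rowSums(is.na(roster[, CESD_ITEMS, drop = FALSE])) > 0
  stage2 <- !stage1 & gad_miss
  stage3 <- !stage1 & !stage2 & cesd_miss
  keep <- !(stage1 | stage2 | stage3)

  report <- structure(list(
    n_initial = n0,
    n_excluded_demographic_or_incomplete = sum(stage1),
    n_excluded_missing_gad = sum(stage2),
    n_excluded_missing_cesd = sum(stage3),
    n_final = sum(keep),
    excluded_ids_by_stage = list(stage1 = roster$id[stage1],
                                 stage2 = roster$id[stage2],
                                 stage3 = roster$id[stage3])),
    class = "screening_report")
  list(retained = roster[keep, , drop = FALSE], report = report)
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Screening report\n")
  cat("  initial (living alone):       ", x$n_initial, "\n")
  cat("  excluded, demographics/>1/3:  ", x$n_excluded_demographic_or_incomplete, "\n")
  cat("  excluded, missing GAD-7:      ", x$n_excluded_missing_gad, "\n")
  cat("  excluded, missing CES-D:      ", x$n_excluded_missing_cesd, "\n")
  cat("  final analytic sample:        ", x$n_final, "\n")
  invisible(x)
}

#' Score the GAD-7 and CES-D-10 scales
#'
#' Totals are plain sums of the item responses; symptom flags use the
#' conventional screening cutoffs (CES-D total >= 10 for depressive symptoms,
#' GAD-7 total >= 5 for anxiety symptoms).
#'
#' @param roster A screened roster with complete item responses.
#' @param cesd_cutoff,gad_cutoff Screening cutoffs (defaults 10 and 5).
#' @return Data frame with `id`, `gad_total` (0-21), `cesd_total` (0-30),
#'   `anxiety_flag`, `depressive_flag`.
#' @export
score_scales <- function(roster, cesd_cutoff = 10L, gad_cutoff = 5L) {
  gad <- as.matrix(roster[, GAD_ITEMS, drop = FALSE])
  cesd <- as.matrix(roster[, CESD_ITEMS, drop = FALSE])
  if (anyNA(gad) || anyNA(cesd))
    stop("score_scales requires complete item responses; run apply_exclusions first")
  data.frame(id = roster$id,
             gad_total = as.integer(rowSums(gad)),
             cesd_total = as.integer(rowSums(cesd)),
             anxiety_flag = rowSums(gad) >= gad_cutoff,
             depressive_flag = rowSums(cesd) >= cesd_cutoff,
             stringsAsFactors = FALSE)
}

#' Per-item descriptive statistics and symptom prevalences
#'
#' @param roster A screened roster with complete item responses.
#' @return A list with `items` (data frame: `node`, `mean`, `sd`, using the
#'   n-1 denominator for SD) and `prevalence` (percentages of respondents
#'   flagged for depressive and anxiety symptoms).
#' @export
descriptives <- function(roster) {
  if (nrow(roster) == 0L) stop("descriptives requires a nonempty roster")
  items <- as.matrix(roster[, ALL_ITEMS, drop = FALSE])
  tab <- data.frame(node = node_labels(),
                    mean = colMeans(items),
                    sd = apply(items, 2, stats::sd),
                    row.names = NULL, stringsAsFactors = FALSE)
  sc <- score_scales(roster)
  prev <- c(depressive_pct = 100 * mean(sc$depressive_flag),
            anxiety_pct = 100 * mean(sc$anxiety_flag))
  list(items = tab, prevalence = prev, n = nrow(roster))
}

#' Assemble the item-response matrix for network estimation
#'
#' @param roster A screened roster with complete item responses.
#' @return An `item_matrix`: integer matrix n x 17 with node labels as
#'   column names and a `communities` attribute.
#' @export
make_item_matrix <- function(roster) {
  m <- as.matrix(roster[, ALL_ITEMS, drop = FALSE])
  if (anyNA(m)) stop("item matrix must be complete; screen the roster first")
  storage.mode(m) <- "integer"
  colnames(m) <- node_labels()
  rownames(m) <- NULL
  attr(m, "communities") <- node_communities()
  class(m) <- c("item_matrix", class(m))
  m
}

#' Write a roster to delimited text
#'
#' @param roster A `participant_roster` data frame.
#' @param path Output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  utils::write.csv(as.data.frame(roster), path, row.names = FALSE, na = "")
  invisible(path)
}
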