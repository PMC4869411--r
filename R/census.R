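#' @keywords internal
"_PACKAGE"

BIOTYPES   <- c("wild", "hybrid")
SELECTIONS <- c("early", "control", "long")
STAGES     <- c("seed", "cotyledon", "flowering")

CENSUS_COLUMNS <- c("population_id", "biotype", "selection", "replicate",
                    "pan", "individual_id", "germinated", "flowered",
                    "fruit_count", "locule_counts")

#' Construct and validate a census table
#'
#' A census table holds one row per planted seed of a common-garden
#' demography experiment: design labels (biotype, selection treatment,
#' replicate population, pan), the individual's fate over the season
#' (germinated, flowered), and its fecundity measurements (total fruit
#' count and the locule counts of up to 10 sampled fruits, semicolon-joined
#' in a single character field so that the table round-trips through CSV).
#'
#' Row-level invariants are enforced: a plant that flowered must have
#' germinated, a positive fruit count implies flowering, and a positive
#' fruit count requires at least one sampled locule count. Violations are
#' rejected with diagnostics naming the offending rows.
#'
#' @param df data frame with columns `population_id`, `biotype`,
#'   `selection`, `replicate`, `pan`, `individual_id`, `germinated`,
#'   `flowered`, `fruit_count`, `locule_counts`.
#' @param check_design if `TRUE`, additionally require every
#'   biotype x selection x replicate combination of the full design to be
#'   present (enforced by default only at the treatment-averaging stage).
#' @return the validated data frame with class `census_table`.
#' @export
census_table <- function(df, check_design = FALSE) {
  if (!is.data.frame(df)) stop("census data must be a data frame")
  if (nrow(df) == 0L) stop("empty census: no rows")
  missing_cols <- setdiff(CENSUS_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("census schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$biotype <- as.character(df$biotype)
  df$selection <- as.character(df$selection)
  bad_bio <- unique(df$biotype[!df$biotype %in% BIOTYPES])
  if (length(bad_bio) > 0L) {
    stop("unknown biotype label(s): ", paste(bad_bio, collapse = ", "),
         " (expected ", paste(BIOTYPES, collapse = "/"), ")")
  }
  bad_sel <- unique(df$selection[!df$selection %in% SELECTIONS])
  if (length(bad_sel) > 0L) {
    stop("unknown selection label(s): ", paste(bad_sel, collapse = ", "),
         " (expected ", paste(SELECTIONS, collapse = "/"), ")")
  }
  df$germinated <- as.logical(df$germinated)
  df$flowered <- as.logical(df$flowered)
  df$fruit_count <- as.integer(df$fruit_count)
  df$locule_counts <- as.character(df$locule_counts)
  df$locule_counts[is.na(df$locule_counts)] <- ""

  viol <- function(idx, what) {
    if (any(idx)) {
      stop("census invariant violated (", what, ") in row(s): ",
           paste(utils::head(which(idx), 10L), collapse = ", "))
    }
  }
  viol(is.na(df$germinated) | is.na(df$flowered), "missing fate")
  viol(df$flowered & !df$germinated, "flowered without germinating")
  viol(is.na(df$fruit_count) | df$fruit_count < 0L, "negative fruit count")
  viol(df$fruit_count > 0L & !df$flowered, "fruits without flowering")
  n_loc <- vapply(parse_locules(df$locule_counts), length, integer(1))
  viol(df$fruit_count > 0L & n_loc == 0L,
       "positive fruit count with no sampled locule counts")

  if (check_design) {
    missing <- missing_design_cells(df)
    if (length(missing) > 0L) {
      stop("incomplete design: missing cell(s) ",
           paste(missing, collapse = "; "))
    }
  }
  class(df) <- c("census_table", "data.frame")
  df
}

missing_design_cells <- function(df) {
  want <- expand.grid(biotype = BIOTYPES, selection = SELECTIONS,
                      replicate = 1:3, stringsAsFactors = FALSE)
  have <- unique(df[, c("biotype", "selection", "replicate")])
  key <- function(x) paste(x$biotype, x$selection, x$replicate, sep = "/")
  setdiff(key(want), key(have))
}

#' Parse semicolon-joined locule counts
#'
#' @param x character vector, each element like `"4;5;3"` (may be empty).
#' @return list of integer vectors.
#' @export
parse_locules <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(v) {
    v <- v[nzchar(trimws(v))]
    as.integer(v)
  })
}

join_locules <- function(lst) {
  vapply(lst, function(v) paste(v, collapse = ";"), character(1))
}

#' Read a census table from delimited text
#'
#' @param path path to a CSV (or other delimited) file, one row per planted
#'   seed; locule counts of sampled fruits are a semicolon-joined subfield.
#' @param sep field separator, `","` by default.
#' @param check_design see [census_table()].
#' @return a validated [census_table()].
#' @export
read_census <- function(path, sep = ",", check_design = FALSE) {
  if (!file.exists(path)) stop("census file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = list(locule_counts = "character"),
                          blank.lines.skip = TRUE)
  if (nrow(df) == 0L) stop("empty census file: ", path)
  census_table(df, check_design = check_design)
}

#' Write a census table to delimited text
#'
#' @param census a [census_table()].
#' @param path output path.
#' @param sep field separator.
#' @export
write_census <- function(census, path, sep = ",") {
  stopifnot(inherits(census, "census_table"))
  utils::write.table(census, path, sep = sep, row.names = FALSE,
                     quote = TRUE)
  invisible(path)
}

#' Estimate seeds per plant from fruit and locule counts
#'
#' Lifetime seed production of a harvested plant is estimated as the mean
#' locule count of the sampled fruits (up to 10 randomly chosen fruits)
#' multiplied by the plant's total fruit count, one seed per locule. A plant
#' with no fruit produced zero seeds.
#'
#' @param fruit_count nonnegative integer, total fruits on the plant.
#' @param locule_counts integer vector of locule counts of the sampled
#'   fruits; must be non-empty when `fruit_count > 0`.
#' @return estimated seed count (numeric scalar).
#' @examples
#' seeds_per_plant(7, c(3, 5, 4))  # 28
#' @export
seeds_per_plant <- function(fruit_count, locule_counts) {
  if (length(fruit_count) != 1L || is.na(fruit_count) || fruit_count < 0)
    stop("fruit_count must be a single nonnegative count")
  if (fruit_count == 0) return(0)
  if (length(locule_counts) == 0L)
    stop("missing measurement: fruit_count > 0 but no locule counts sampled")
  mean(locule_counts) * fruit_count
}

#' Estimate vital rates for one experimental population
#'
#' The four demographic parameters of the annual life cycle are estimated
#' by pooling all pans of a replicate population:
#' \describe{
#'   \item{g}{germination probability, germinants / seeds planted}
#'   \item{s}{survival to flowering, flowerers / germinants}
#'   \item{f}{fecundity, mean estimated seeds per flowering plant
#'     ([seeds_per_plant()]); flowering plants harvested with zero fruit
#'     contribute 0 to the mean}
#'   \item{d}{seed dormancy/mortality. The experiment cannot separate
#'     dormancy from death in the seed stage, so by default the
#'     non-germinating fraction is kept as a single pooled parameter,
#'     `d = 1 - g`; pass `dormancy` to override (e.g. `0` to treat all
#'     non-germinating seeds as dead).}
#' }
#'
#' @param census a [census_table()].
#' @param population_id population to estimate (a value of the
#'   `population_id` column).
#' @param dormancy optional numeric override for `d` (must satisfy
#'   `d + g <= 1`).
#' @return an object of class `vital_rates`: a list with `d`, `g`, `s`,
#'   `f`, the supporting counts `n_seeds`, `n_germinants`, `n_flowerers`,
#'   a `s_defined` flag (FALSE when no seed germinated, in which case `s`
#'   is a flagged zero and lambda degenerates to `d`), and the design
#'   `labels`.
#' @export
estimate_vital_rates <- function(census, population_id, dormancy = NULL) {
  stopifnot(inherits(census, "census_table"))
  rows <- census[census$population_id == population_id, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("unknown population_id: ", population_id)

  n_seeds <- nrow(rows)
  n_germ <- sum(rows$germinated)
  n_flow <- sum(rows$flowered)
  g <- n_germ / n_seeds
  s_defined <- n_germ > 0L
  if (s_defined) {
    s <- n_flow / n_germ
  } else {
    s <- 0
    warning("degenerate population ", population_id,
            ": no germinants; s undefined (returned as 0, lambda = d)")
  }
  if (n_flow > 0L) {
    fl <- rows[rows$flowered, , drop = FALSE]
    locs <- parse_locules(fl$locule_counts)
    f <- mean(vapply(seq_len(nrow(fl)), function(i)
      seeds_per_plant(fl$fruit_count[i], locs[[i]]), numeric(1)))
  } else {
    f <- 0
  }
  d <- if (is.null(dormancy)) 1 - g else dormancy
  if (d < 0 || d + g > 1 + 1e-12)
    stop("infeasible dormancy: need 0 <= d and d + g <= 1 (d = ", d,
         ", g = ", g, ")")

  structure(list(
    d = d, g = g, s = s, f = f,
    n_seeds = n_seeds, n_germinants = n_germ, n_flowerers = n_flow,
    s_defined = s_defined,
    labels = list(population_id = population_id,
                  biotype = rows$biotype[1L],
                  selection = rows$selection[1L],
                  replicate = rows$replicate[1L])
  ), class = "vital_rates")
}

#' @export
print.vital_rates <- function(x, ...) {
  cat(sprintf("Vital rates for population %s (%s / %s / rep %s)\n",
              x$labels$population_id, x$labels$biotype,
              x$labels$selection, x$labels$replicate))
  cat(sprintf("  d = %.4f  g = %.4f  s = %.4f  f = %.2f\n",
              x$d, x$g, x$s, x$f))
  cat(sprintf("  counts: %d seeds -> %d germinants -> %d flowerers\n",
              x$n_seeds, x$n_germinants, x$n_flowerers))
  if (!x$s_defined) cat("  [degenerate: no germinants, s flagged]\n")
  invisible(x)
}

#' Vital-rate summary table for all populations
#'
#' One row per replicate population with the design labels, the four vital
#' rates, supporting counts, and (optionally) the population growth rate
#' lambda of the corresponding projection matrix.
#'
#' @inheritParams estimate_vital_rates
#' @param lambda add a `lambda` column computed from each population's
#'   projection matrix? Default `TRUE`.
#' @return data frame with one row per population, ordered by biotype,
#'   selection, replicate.
#' @export
vital_rate_table <- function(census, dormancy = NULL, lambda = TRUE) {
  stopifnot(inherits(census, "census_table"))
  pops <- unique(census$population_id)
  rows <- lapply(pops, function(p) {
    vr <- estimate_vital_rates(census, p, dormancy = dormancy)
    data.frame(population_id = p,
               biotype = vr$labels$biotype,
               selection = vr$labels$selection,
               replicate = vr$labels$replicate,
               d = vr$d, g = vr$g, s = vr$s, f = vr$f,
               n_seeds = vr$n_seeds, n_germinants = vr$n_germinants,
               n_flowerers = vr$n_flowerers,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (lambda) {
    out$lambda <- vapply(pops, function(p) {
      vr <- estimate_vital_rates(census, p, dormancy = dormancy)
      lambda1(build_matrix(vr))
    }, numeric(1))
  }
  ord <- order(match(out$biotype, BIOTYPES),
               match(out$selection, SELECTIONS), out$replicate)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
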