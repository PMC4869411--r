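VITAL_ELEMENT_NAMES <- c(
  "a11" = "dormancy/mortality",
  "a21" = "germination",
  "a32" = "flowering survival",
  "a13" = "fecundity")

# element index map for the structural nonzeros
STRUCTURAL_IJ <- cbind(i = c(1L, 2L, 3L, 1L), j = c(1L, 1L, 2L, 3L))
rownames(STRUCTURAL_IJ) <- names(VITAL_ELEMENT_NAMES)

matrix_labels <- function(A) attr(A, "labels")

#' Build projection matrices for every population in a census
#'
#' @inheritParams estimate_vital_rates
#' @return named list of `projection_matrix`, one per population.
#' @export
matrices_from_census <- function(census, dormancy = NULL) {
  stopifnot(inherits(census, "census_table"))
  pops <- unique(census$population_id)
  out <- lapply(pops, function(p)
    build_matrix(estimate_vital_rates(census, p, dormancy = dormancy)))
  names(out) <- pops
  out
}

#' Element-wise mean of projection matrices
#'
#' Transition frequencies are averaged element-wise; averaging preserves
#' the 4-transition skeleton and feasibility (`d + g <= 1`).
#'
#' @param matrices list of `projection_matrix`.
#' @param labels labels for the result.
#' @return a `projection_matrix`.
#' @export
mean_matrix <- function(matrices, labels = NULL) {
  if (length(matrices) == 0L) stop("cannot average an empty set of matrices")
  ms <- lapply(matrices, unclass_matrix)
  M <- Reduce(`+`, ms) / length(ms)
  # exact idempotence: the mean of identical matrices is that matrix
  # (floating-point summation would otherwise leave ~1e-16 residue)
  if (all(vapply(ms, function(m) identical(m, ms[[1]]), logical(1))))
    M <- ms[[1]]
  dimnames(M) <- list(STAGES, STAGES)
  attr(M, "labels") <- labels
  class(M) <- c("projection_matrix", class(M))
  M
}

#' Reference matrix of the design
#'
#' The baseline against which treatment effects on lambda are measured:
#' by default the element-wise mean of the 6 randomly-mating (control)
#' population matrices of both biotypes; optionally the grand mean of all
#' 18 matrices (for sensitivity analysis of the reference choice).
#'
#' @param matrices list of labelled `projection_matrix` covering the
#'   design.
#' @param type `"control"` (default) or `"grand"`.
#' @return a `projection_matrix` tagged as the reference.
#' @export
reference_matrix <- function(matrices, type = c("control", "grand")) {
  type <- match.arg(type)
  if (length(matrices) == 0L) stop("no matrices supplied")
  keep <- if (type == "control") {
    Filter(function(A) matrix_labels(A)$selection == "control", matrices)
  } else matrices
  if (length(keep) == 0L) stop("no control matrices found for reference")
  mean_matrix(keep, labels = list(level = paste0("reference(", type, ")")))
}

#' Two-stage treatment averaging of the design matrices
#'
#' Pooled treatment matrices are formed in two stages: replicate matrices
#' are first averaged within each biotype x selection cell (6 cell means
#' `A^{gs}`); biotype means `A^{g.}` are then the average of that biotype's
#' 3 cell means, and selection means `A^{.s}` the average of that
#' treatment's 2 cell means. This is deliberately not a grand pool of
#' replicates — each cell enters a marginal mean with equal weight.
#'
#' @param matrices list of labelled `projection_matrix` for the full
#'   2 biotype x 3 selection x 3 replicate design.
#' @return list with elements `cell` (named `biotype/selection`),
#'   `biotype`, and `selection`, each a named list of
#'   `projection_matrix`.
#' @export
treatment_matrices <- function(matrices) {
  labs <- lapply(matrices, matrix_labels)
  bio <- vapply(labs, function(l) l$biotype, character(1))
  sel <- vapply(labs, function(l) l$selection, character(1))
  cells <- list()
  for (b in BIOTYPES) for (s in SELECTIONS) {
    idx <- which(bio == b & sel == s)
    if (length(idx) == 0L)
      stop("missing design cell: ", b, "/", s)
    cells[[paste(b, s, sep = "/")]] <-
      mean_matrix(matrices[idx], labels = list(biotype = b, selection = s))
  }
  biotype_means <- lapply(BIOTYPES, function(b)
    mean_matrix(cells[paste(b, SELECTIONS, sep = "/")],
                labels = list(biotype = b, selection = ".")))
  names(biotype_means) <- BIOTYPES
  selection_means <- lapply(SELECTIONS, function(s)
    mean_matrix(cells[paste(BIOTYPES, s, sep = "/")],
                labels = list(biotype = ".", selection = s)))
  names(selection_means) <- SELECTIONS
  list(cell = cells, biotype = biotype_means, selection = selection_means)
}

#' One-way LTRE comparison of two matrices
#'
#' Decomposes the difference in lambda between a treatment matrix and a
#' reference matrix into per-element contributions
#' \deqn{c_{ij} = (a_{ij}^{trt} - a_{ij}^{ref}) \cdot
#'   \left.\frac{\partial\lambda}{\partial a_{ij}}\right|_{(A^{trt} +
#'   A^{ref})/2}}
#' with the sensitivities evaluated at the matrix halfway between the two
#' (the midpoint convention). The contribution sum approximates the exact
#' lambda difference to first order.
#'
#' @param treatment,reference `projection_matrix` objects.
#' @return list with `delta_lambda` (exact), `contributions` (3x3 matrix),
#'   `first_order` (sum of contributions), `midpoint` sensitivities.
#' @export
ltre_compare <- function(treatment, reference) {
  At <- unclass_matrix(as.matrix(treatment))
  Ar <- unclass_matrix(as.matrix(reference))
  mid <- (At + Ar) / 2
  S <- perturbation(mid)$S
  C <- (At - Ar) * S
  dimnames(C) <- list(STAGES, STAGES)
  list(delta_lambda = lambda1(At) - lambda1(Ar),
       contributions = C,
       first_order = sum(C),
       sensitivity = S)
}

#' Fit a two-way fixed-effect life table response experiment
#'
#' Models the population growth rate of each biotype x selection treatment
#' combination as
#' \deqn{\lambda^{gs} = \lambda^{(\cdot\cdot)} + \alpha^g + \beta^s +
#'   \alpha\beta^{gs}}
#' where \eqn{\lambda^{(\cdot\cdot)}} is the growth rate of the reference
#' matrix, \eqn{\alpha^g} the main effect of biotype level g,
#' \eqn{\beta^s} the main effect of selection level s, and
#' \eqn{\alpha\beta^{gs}} their interaction. Effects are computed both
#' ways:
#' \itemize{
#'   \item exactly, as lambda differences
#'     (\eqn{\alpha^g = \lambda^{g\cdot} - \lambda^{(\cdot\cdot)}}, etc.,
#'     with the interaction as the residual
#'     \eqn{\lambda^{gs} - \lambda^{(\cdot\cdot)} - \alpha^g - \beta^s},
#'     so the decomposition is additive by construction), and
#'   \item to first order, as sums of per-matrix-element contributions
#'     \eqn{c_{ij} = (a_{ij}^{level} - a_{ij}^{(\cdot\cdot)})\,
#'     (\partial\lambda/\partial a_{ij})} with sensitivities evaluated
#'     halfway between the level matrix and the reference
#'     ([ltre_compare()]). Interaction contributions are the
#'     cell-vs-reference contributions minus the two first-order main
#'     effect contributions, element-wise, keeping all terms on the same
#'     first-order scale.
#' }
#' The two versions differ by the curvature of lambda in the vital rates;
#' contributions are what gets plotted, exact differences are what they
#' approximate.
#'
#' @param x a named list of 18 labelled `projection_matrix` (one per
#'   replicate population), or a [census_table()].
#' @param reference `"control"` (mean of the 6 randomly-mating population
#'   matrices, the default) or `"grand"` (mean of all 18).
#' @param ... passed to methods; for the census method, `dormancy` is
#'   forwarded to [estimate_vital_rates()].
#' @return an object of class `ltre`; see Details. Components include
#'   `lambda_ref`, `lambda` (per cell / biotype / selection level),
#'   `effects` (exact and first-order, per level), `contributions`
#'   (per-level 3x3 matrices), the pooled matrices and the reference.
#' @seealso [summary.ltre()], [contribution_table()], [plot.ltre()]
#' @export
ltre <- function(x, ...) UseMethod("ltre")

#' @rdname ltre
#' @export
ltre.census_table <- function(x, reference = c("control", "grand"),
                              dormancy = NULL, ...) {
  ltre(matrices_from_census(x, dormancy = dormancy),
       reference = reference, ...)
}

#' @rdname ltre
#' @export
ltre.list <- function(x, reference = c("control", "grand"), ...) {
  reference <- match.arg(reference)
  pooled <- treatment_matrices(x)
  ref <- reference_matrix(x, type = reference)
  lam_ref <- lambda1(ref)

  cmp_level <- function(level_matrices) lapply(level_matrices, ltre_compare,
                                               reference = ref)
  bio_cmp <- cmp_level(pooled$biotype)
  sel_cmp <- cmp_level(pooled$selection)
  cell_cmp <- cmp_level(pooled$cell)

  eff <- function(cmps, how) vapply(cmps, `[[`, numeric(1), how)
  alpha_exact <- eff(bio_cmp, "delta_lambda")
  beta_exact <- eff(sel_cmp, "delta_lambda")
  alpha_fo <- eff(bio_cmp, "first_order")
  beta_fo <- eff(sel_cmp, "first_order")

  # interaction: cell-vs-reference minus the two main effects
  ab_exact <- ab_fo <- stats::setNames(
    numeric(length(cell_cmp)), names(cell_cmp))
  ab_contrib <- vector("list", length(cell_cmp))
  names(ab_contrib) <- names(cell_cmp)
  for (cell in names(cell_cmp)) {
    parts <- strsplit(cell, "/", fixed = TRUE)[[1]]
    b <- parts[1]; s <- parts[2]
    ab_exact[cell] <- cell_cmp[[cell]]$delta_lambda -
      alpha_exact[b] - beta_exact[s]
    ab_contrib[[cell]] <- cell_cmp[[cell]]$contributions -
      bio_cmp[[b]]$contributions - sel_cmp[[s]]$contributions
    ab_fo[cell] <- sum(ab_contrib[[cell]])
  }

  structure(list(
    reference = ref,
    reference_type = reference,
    lambda_ref = lam_ref,
    lambda = list(
      cell = vapply(pooled$cell, lambda1, numeric(1)),
      biotype = vapply(pooled$biotype, lambda1, numeric(1)),
      selection = vapply(pooled$selection, lambda1, numeric(1))),
    effects = list(
      exact = list(biotype = alpha_exact, selection = beta_exact,
                   interaction = ab_exact),
      first_order = list(biotype = alpha_fo, selection = beta_fo,
                         interaction = ab_fo)),
    contributions = list(
      biotype = lapply(bio_cmp, `[[`, "contributions"),
      selection = lapply(sel_cmp, `[[`, "contributions"),
      interaction = ab_contrib,
      cell = lapply(cell_cmp, `[[`, "contributions")),
    pooled = pooled,
    matrices = x
  ), class = "ltre")
}

#' @export
print.ltre <- function(x, digits = 4, ...) {
  cat("Two-way fixed-effect LTRE\n")
  cat("  reference:", x$reference_type, " lambda_ref =",
      format(x$lambda_ref, digits = digits), "\n")
  cat("  biotype effects (exact):\n")
  print(round(x$effects$exact$biotype, digits))
  cat("  selection effects (exact):\n")
  print(round(x$effects$exact$selection, digits))
  cat("  interaction effects (exact):\n")
  print(round(x$effects$exact$interaction, digits))
  invisible(x)
}

#' @export
summary.ltre <- function(object, ...) {
  rows <- do.call(rbind, lapply(
    c("biotype", "selection", "interaction"), function(kind) {
      ex <- object$effects$exact[[kind]]
      fo <- object$effects$first_order[[kind]]
      data.frame(effect = kind, level = names(ex),
                 exact = unname(ex), first_order = unname(fo),
                 stringsAsFactors = FALSE)
    }))
  rows$abs_error <- abs(rows$exact - rows$first_order)
  out <- list(table = rows, lambda_ref = object$lambda_ref,
              lambda = object$lambda,
              reference_type = object$reference_type)
  class(out) <- "summary.ltre"
  out
}

#' @export
print.summary.ltre <- function(x, digits = 4, ...) {
  cat("LTRE decomposition (reference:", x$reference_type,
      ", lambda_ref =", format(x$lambda_ref, digits = digits), ")\n")
  cat("lambda by treatment level:\n")
  cat("  biotype:  ", paste(names(x$lambda$biotype),
      format(x$lambda$biotype, digits = digits), collapse = "  "), "\n")
  cat("  selection:", paste(names(x$lambda$selection),
      format(x$lambda$selection, digits = digits), collapse = "  "), "\n")
  cat("\nEffects on lambda (exact difference vs first-order contribution",
      "sum):\n")
  tab <- x$table
  tab$exact <- round(tab$exact, digits)
  tab$first_order <- round(tab$first_order, digits)
  tab$abs_error <- signif(tab$abs_error, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
#' @param object an `ltre` fit.
#' @param type `"exact"` (default) or `"first_order"`.
#' @rdname ltre
coef.ltre <- function(object, type = c("exact", "first_order"), ...) {
  type <- match.arg(type)
  e <- object$effects[[type]]
  c(stats::setNames(e$biotype, paste0("biotype:", names(e$biotype))),
    stats::setNames(e$selection, paste0("selection:", names(e$selection))),
    stats::setNames(e$interaction,
                    paste0("interaction:", names(e$interaction))))
}

#' Tidy table of LTRE contributions by vital rate
#'
#' Maps the per-matrix-element contributions onto the four named vital
#' rates (a11 = dormancy/mortality, a21 = germination, a32 = flowering
#' survival, a13 = fecundity) in long format, suitable for bar plots of
#' the decomposition.
#'
#' @param decomp an `ltre` fit.
#' @param effects which effect families to include.
#' @return data frame with columns `effect`, `level`, `vital_rate`,
#'   `element`, `contribution`.
#' @export
contribution_table <- function(decomp,
                               effects = c("biotype", "selection",
                                           "interaction")) {
  stopifnot(inherits(decomp, "ltre"))
  effects <- match.arg(effects, several.ok = TRUE)
  rows <- list()
  for (kind in effects) {
    for (level in names(decomp$contributions[[kind]])) {
      C <- decomp$contributions[[kind]][[level]]
      contrib <- C[STRUCTURAL_IJ]
      rows[[paste(kind, level)]] <- data.frame(
        effect = kind, level = level,
        vital_rate = unname(VITAL_ELEMENT_NAMES),
        element = names(VITAL_ELEMENT_NAMES),
        contribution = contrib, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot LTRE contributions
#'
#' Grouped bar plot of per-vital-rate contributions to lambda differences,
#' one group of bars per effect level.
#'
#' @param x an `ltre` fit.
#' @param effects effect families to plot (see [contribution_table()]).
#' @param ... further arguments passed to [graphics::barplot()].
#' @return invisibly, the matrix of plotted contributions.
#' @export
plot.ltre <- function(x, effects = c("biotype", "selection"), ...) {
  tab <- contribution_table(x, effects = effects)
  levels_ <- unique(paste(tab$effect, tab$level, sep = ":"))
  M <- matrix(tab$contribution, nrow = 4,
              dimnames = list(unname(VITAL_ELEMENT_NAMES), levels_))
  graphics::barplot(M, beside = TRUE, legend.text = rownames(M),
                    ylab = "contribution to delta lambda",
                    las = 2, ...)
  graphics::abline(h = 0)
  invisible(M)
}

#' Compare a treatment cell with its control within one biotype
#'
#' Decomposition of the lambda difference between a selected lineage and
#' the randomly-mating control of the same biotype — the within-biotype
#' view of the design. The reference can be either the biotype's own
#' control cell mean (`"biotype"`) or the pooled two-biotype control
#' reference (`"pooled"`); both conventions are legitimate readings of a
#' within-biotype comparison and are provided side by side.
#'
#' @param matrices the 18 labelled replicate matrices.
#' @param biotype,selection the cell to compare (selection != "control").
#' @param control `"biotype"` (default) or `"pooled"`.
#' @return an [ltre_compare()] result.
#' @export
within_biotype_comparison <- function(matrices, biotype, selection,
                                      control = c("biotype", "pooled")) {
  control <- match.arg(control)
  biotype <- match.arg(biotype, BIOTYPES)
  selection <- match.arg(selection, setdiff(SELECTIONS, "control"))
  pooled <- treatment_matrices(matrices)
  trt <- pooled$cell[[paste(biotype, selection, sep = "/")]]
  ref <- if (control == "biotype") {
    pooled$cell[[paste(biotype, "control", sep = "/")]]
  } else {
    reference_matrix(matrices, type = "control")
  }
  ltre_compare(trt, ref)
}
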