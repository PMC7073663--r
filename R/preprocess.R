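trial_covariate_names <- function(table) {
  setdiff(names(table), c("patient_id", "arm", "outcome"))
}

trial_schema <- function(table) attr(table, "schema")

#' Validate a patient-level trial table
#'
#' Checks the structural invariants: unique patient ids, non-missing arm
#' labels restricted to TAU/BLEND, and outcomes inside the 0-27 PHQ-9
#' range when present.
#'
#' @param table trial table (data frame).
#' @return the table, invisibly; errors describe the first violation.
#' @export
validate_trial <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("patient_id", "arm", "outcome")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("trial table lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyDuplicated(table$patient_id))
    stop("duplicate patient ids", call. = FALSE)
  arm <- as.character(table$arm)
  if (anyNA(arm)) stop("missing arm labels", call. = FALSE)
  bad <- setdiff(unique(arm), c("TAU", "BLEND"))
  if (length(bad))
    stop("unknown arm label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  y <- table$outcome
  if (any(!is.na(y) & (y < 0 | y > 27)))
    stop("outcome outside the 0-27 PHQ-9 range", call. = FALSE)
  invisible(table)
}

#' Restrict the cohort to treatment completers
#'
#' Drops patients whose 12-week outcome is missing, mirroring the
#' completer-inclusion rule used before imputation and modeling. The
#' operation is idempotent and preserves row order.
#'
#' @param table trial table.
#' @return list with `table` (retained rows) and `report` (removed count
#'   and per-arm retained counts).
#' @export
filter_completers <- function(table) {
  validate_trial(table)
  keep <- !is.na(table$outcome)
  out <- table[keep, , drop = FALSE]
  attr(out, "schema") <- trial_schema(table)
  n_tau <- sum(out$arm == "TAU")
  n_blend <- sum(out$arm == "BLEND")
  if (n_tau == 0L || n_blend == 0L)
    stop("an arm has no completers; per-arm models cannot be fitted", call. = FALSE)
  list(table = out,
       report = list(removed = sum(!keep), retained = nrow(out),
                     retained_tau = n_tau, retained_blend = n_blend))
}

#' Screen out covariates with excessive missingness
#'
#' Covariates whose missing fraction is at or above `threshold` (default:
#' the strict <50% acceptability rule, computed on the completer-filtered
#' table) are removed from the candidate predictor set.
#'
#' @param table trial table (normally post [filter_completers()]).
#' @param threshold drop when missing fraction >= threshold; in (0, 1].
#' @return list with `table` and `dropped` (named missing fractions of the
#'   removed covariates).
#' @export
screen_missingness <- function(table, threshold = 0.50) {
  stopifnot(threshold > 0, threshold <= 1)
  covs <- trial_covariate_names(table)
  frac <- vapply(covs, function(v) mean(is.na(table[[v]])), 0)
  drop <- covs[frac >= threshold]
  out <- table[, setdiff(names(table), drop), drop = FALSE]
  schema <- trial_schema(table)
  if (!is.null(schema)) {
    keep_schema <- vapply(schema, function(cv) !cv$name %in% drop, TRUE)
    attr(out, "schema") <- schema[keep_schema]
  }
  list(table = out, dropped = frac[drop])
}

encode_levels_map <- function(table) {
  schema <- trial_schema(table)
  covs <- trial_covariate_names(table)
  map <- list()
  for (v in covs) {
    x <- table[[v]]
    if (is.factor(x) || is.character(x)) {
      lev <- NULL
      if (!is.null(schema)) {
        idx <- which(vapply(schema, `[[`, "", "name") == v)
        if (length(idx)) lev <- schema[[idx]]$levels
      }
      map[[v]] <- sort(lev %||% unique(as.character(x[!is.na(x)])))
    }
  }
  map
}

#' Encode a trial table as a numeric design matrix
#'
#' Continuous and count covariates pass through unchanged; a binary
#' covariate becomes a single 0/1 indicator of its second sorted level;
#' a k-level nominal is split into k-1 indicator columns against the
#' lexicographically first level as reference. Column metadata records,
#' for every design column, the source variable, the encoded category and
#' the reference level, which suffices to reconstruct the original
#' categories.
#'
#' @param table trial table with no missing covariate values (run after
#'   imputation).
#' @param meta optional `column_meta` from a previous encoding; when given,
#'   the same columns/levels are enforced and an unseen category raises an
#'   error naming the variable and level.
#' @return object of class `coded_matrix`: list with `x` (numeric matrix,
#'   rownames = patient ids), `meta` (column metadata data frame), plus
#'   the aligned `patient_id`, `arm` and `outcome` vectors.
#' @export
encode <- function(table, meta = NULL) {
  validate_trial(table)
  covs <- trial_covariate_names(table)
  if (!length(covs)) stop("no covariates to encode", call. = FALSE)
  na_cov <- covs[vapply(covs, function(v) anyNA(table[[v]]), TRUE)]
  if (length(na_cov))
    stop("missing covariate values (impute first): ",
         paste(na_cov, collapse = ", "), call. = FALSE)

  if (is.null(meta)) {
    lmap <- encode_levels_map(table)
  } else {
    covs <- unique(meta$source)
    lmap <- lapply(split(meta, meta$source), function(m) {
      if (all(m$category == "continuous")) NULL else sort(unique(c(m$reference, m$category)))
    })
    lmap <- Filter(Negate(is.null), lmap)
  }

  cols <- list(); rows_meta <- list()
  for (v in covs) {
    if (!v %in% names(table)) stop("variable absent from table: ", v, call. = FALSE)
    x <- table[[v]]
    if (is.null(lmap[[v]])) {
      cols[[v]] <- as.numeric(x)
      rows_meta[[v]] <- data.frame(column = v, source = v,
                                   category = "continuous", reference = NA_character_)
    } else {
      lev <- lmap[[v]]
      xv <- as.character(x)
      unseen <- setdiff(unique(xv), lev)
      if (length(unseen))
        stop(sprintf("unseen category for '%s': %s", v, paste(unseen, collapse = ", ")),
             call. = FALSE)
      for (lv in lev[-1L]) {
        cn <- if (length(lev) == 2L) v else paste(v, lv, sep = "_")
        cols[[cn]] <- as.numeric(xv == lv)
        rows_meta[[cn]] <- data.frame(column = cn, source = v,
                                      category = lv, reference = lev[1L])
      }
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- as.character(table$patient_id)
  out_meta <- do.call(rbind, rows_meta)
  rownames(out_meta) <- NULL
  if (!is.null(meta)) {
    x <- x[, meta$column, drop = FALSE]
    out_meta <- out_meta[match(meta$column, out_meta$column), , drop = FALSE]
  }
  structure(list(x = x, meta = out_meta,
                 patient_id = as.character(table$patient_id),
                 arm = as.character(table$arm),
                 outcome = table$outcome),
            class = "coded_matrix")
}

#' Reconstruct categorical labels from an encoded matrix
#'
#' Inverse of [encode()] up to the reference-level convention: indicator
#' blocks are folded back into a single labelled column.
#'
#' @param coded a `coded_matrix`.
#' @return data frame of covariates on the original (labelled) scale.
#' @export
decode <- function(coded) {
  stopifnot(inherits(coded, "coded_matrix"))
  meta <- coded$meta
  out <- list()
  for (v in unique(meta$source)) {
    m <- meta[meta$source == v, , drop = FALSE]
    if (all(m$category == "continuous")) {
      out[[v]] <- coded$x[, m$column[1L]]
    } else {
      lab <- rep(m$reference[1L], nrow(coded$x))
      for (i in seq_len(nrow(m)))
        lab[coded$x[, m$column[i]] == 1] <- m$category[i]
      out[[v]] <- lab
    }
  }
  as.data.frame(out, optional = TRUE)
}
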