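AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Parse an amino-acid substitution code
#'
#' Codes use the field's canonical text form, e.g. `"V136E"`: wild-type
#' residue, 1-based protein position, substituted residue.
#'
#' @param code Character vector of codes.
#' @return Data frame with columns `wt_aa`, `position`, `new_aa`.
#' @export
parse_mutation_code <- function(code) {
  m <- regmatches(code, regexec("^([A-Z])([0-9]+)([A-Z])$", code))
  bad <- vapply(m, length, 1L) != 4L
  if (!any(bad)) {
    wt <- vapply(m, `[`, "", 2L); pos <- as.integer(vapply(m, `[`, "", 3L))
    new <- vapply(m, `[`, "", 4L)
    bad <- !(wt %in% AA_ALPHABET) | !(new %in% AA_ALPHABET) | wt == new | pos < 1L
  }
  if (any(bad))
    stop("invalid mutation code(s): ", paste(code[bad], collapse = ", "),
         call. = FALSE)
  data.frame(wt_aa = vapply(m, `[`, "", 2L),
             position = as.integer(vapply(m, `[`, "", 3L)),
             new_aa = vapply(m, `[`, "", 4L))
}

#' Construct a genotype
#'
#' A genotype is an ordered set of substitution codes relative to the
#' wild-type sequence; the empty set is the wild type. Positions must be
#' unique within a genotype. Codes are stored sorted by position.
#'
#' @param codes Character vector of substitution codes (may be empty).
#' @return Character vector of class `genotype`, canonically ordered.
#' @export
genotype <- function(codes = character()) {
  codes <- as.character(codes[nzchar(codes)])
  if (length(codes)) {
    p <- parse_mutation_code(codes)
    if (anyDuplicated(p$position))
      stop("genotype: duplicate positions in ", paste(codes, collapse = ","),
           call. = FALSE)
    codes <- codes[order(p$position, p$new_aa)]
  }
  structure(codes, class = "genotype")
}

#' @export
format.genotype <- function(x, ...) if (length(x)) paste(unclass(x), collapse = ",") else ""

#' @export
print.genotype <- function(x, ...) {
  cat(if (length(x)) format(x) else "<wild type>", "\n")
  invisible(x)
}

#' A variant record: genotype plus phenotype posterior
#'
#' @param genotype A [genotype()] (or character vector of codes).
#' @param posterior A [hill_posterior()].
#' @param quality Relative evidence weight (e.g. a barcode-read proxy),
#'   dimensionless, >= 0; lower quality means a noisier measurement.
#' @param id Optional variant identifier.
#' @return Object of class `variant_record`.
#' @export
variant_record <- function(genotype, posterior, quality = 1, id = NULL) {
  if (!inherits(genotype, "genotype")) genotype <- genotype(genotype)
  stopifnot(inherits(posterior, "hill_posterior"),
            is.numeric(quality), length(quality) == 1L, quality >= 0)
  structure(list(genotype = genotype, posterior = posterior,
                 quality = quality, id = id), class = "variant_record")
}

#' A genotype-phenotype landscape
#'
#' Collection of variant records with a mutation vocabulary (the union of
#' all substitution codes observed, ordered by position) and a cached
#' summary table used by queries and selection.
#'
#' @param records List of [variant_record()]s.
#' @return Object of class `landscape` with elements `records`,
#'   `vocabulary` and `summary` (a data frame with one row per record:
#'   `variant`, `mutation_codes`, `n_mut`, posterior medians `g0`, `ginf`,
#'   `ec50`, `n` on natural scales, log-scale means/SDs, `quality`,
#'   `inverted`).
#' @export
landscape <- function(records) {
  stopifnot(is.list(records),
            all(vapply(records, inherits, TRUE, "variant_record")))
  ids <- vapply(seq_along(records), function(i) {
    if (is.null(records[[i]]$id)) sprintf("v%05d", i) else as.character(records[[i]]$id)
  }, "")
  if (anyDuplicated(ids)) stop("landscape: duplicate variant ids", call. = FALSE)
  for (i in seq_along(records)) records[[i]]$id <- ids[i]
  codes <- unique(unlist(lapply(records, function(r) unclass(r$genotype))))
  if (length(codes)) {
    p <- parse_mutation_code(codes)
    codes <- codes[order(p$position, p$new_aa)]
  }
  structure(list(records = records,
                 vocabulary = as.character(codes),
                 summary = landscape_summary_table(records, ids)),
            class = "landscape")
}

landscape_summary_table <- function(records, ids) {
  if (!length(records))
    return(data.frame(variant = character(), mutation_codes = character(),
                      n_mut = integer(), g0 = numeric(), ginf = numeric(),
                      ec50 = numeric(), n = numeric(), quality = numeric(),
                      inverted = logical()))
  pts <- t(vapply(records, function(r) posterior_point(r$posterior), numeric(4)))
  data.frame(
    variant = ids,
    mutation_codes = vapply(records, function(r) format(r$genotype), ""),
    n_mut = vapply(records, function(r) length(r$genotype), 1L),
    g0 = pts[, "g0"], ginf = pts[, "ginf"], ec50 = pts[, "ec50"], n = pts[, "n"],
    quality = vapply(records, function(r) r$quality, 1),
    inverted = pts[, "ginf"] < pts[, "g0"],
    row.names = NULL)
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("Genotype-phenotype landscape: %d variants, %d distinct mutations\n",
              length(x$records), length(x$vocabulary)))
  if (nrow(x$summary)) {
    cat(sprintf("  EC50 median range: %.3g - %.3g umol/L; inverted: %d (%.2f%%)\n",
                min(x$summary$ec50), max(x$summary$ec50),
                sum(x$summary$inverted), 100 * mean(x$summary$inverted)))
  }
  invisible(x)
}

#' @export
length.landscape <- function(x) length(x$records)

landscape_cols <- c("variant", "mutation_codes", "log_g0", "log_g0_err",
                    "log_ginf", "log_ginf_err", "log_ec50", "log_ec50_err",
                    "n", "n_err")

#' Write a landscape to CSV (summary plus posterior-sample sidecar)
#'
#' The summary CSV carries one row per variant with posterior means and
#' one-SD uncertainties on base-10 log scales (`log_g0`, `log_ginf`,
#' `log_ec50`; linear `n`), the comma-separated mutation codes (empty
#' string for wild type) and a `quality` column. The sidecar CSV carries
#' the posterior draws (`variant`, `draw`, four parameter columns).
#'
#' @param x A [landscape()].
#' @param path Output CSV path; the sidecar is written next to it with a
#'   `_samples.csv` suffix unless `sidecar_path` is given.
#' @param sidecar_path Optional sidecar path.
#' @return Invisibly, the two paths.
#' @export
save_landscape <- function(x, path, sidecar_path = NULL) {
  stopifnot(inherits(x, "landscape"))
  if (is.null(sidecar_path)) sidecar_path <- sidecar_name(path)
  s <- x$summary
  main <- data.frame(
    variant = s$variant, mutation_codes = s$mutation_codes,
    log_g0 = NA_real_, log_g0_err = NA_real_,
    log_ginf = NA_real_, log_ginf_err = NA_real_,
    log_ec50 = NA_real_, log_ec50_err = NA_real_,
    n = NA_real_, n_err = NA_real_, quality = s$quality)
  side <- vector("list", length(x$records))
  for (i in seq_along(x$records)) {
    r <- x$records[[i]]
    main[i, c("log_g0", "log_ginf", "log_ec50", "n")] <-
      r$posterior$mean[c("log_g0", "log_ginf", "log_ec50", "n")]
    main[i, c("log_g0_err", "log_ginf_err", "log_ec50_err", "n_err")] <-
      r$posterior$sd[c("log_g0", "log_ginf", "log_ec50", "n")]
    sm <- r$posterior$samples
    side[[i]] <- data.frame(variant = r$id, draw = seq_len(nrow(sm)),
                            log_g0 = sm[, "log_g0"], log_ginf = sm[, "log_ginf"],
                            log_ec50 = sm[, "log_ec50"], n = sm[, "n"])
  }
  utils::write.csv(main, path, row.names = FALSE)
  utils::write.csv(do.call(rbind, side), sidecar_path, row.names = FALSE,
                   quote = FALSE)
  invisible(c(path, sidecar_path))
}

sidecar_name <- function(path) sub("(\\.csv)(\\.gz)?$", "_samples\\1\\2", path)

#' Load a landscape from CSV (summary plus posterior-sample sidecar)
#'
#' Inverse of [save_landscape()]. Malformed mutation codes and non-finite
#' parameter values are reported with their row numbers.
#'
#' @param path Summary CSV path (optionally gzipped).
#' @param sidecar_path Posterior-sample sidecar path (default: derived
#'   from `path`).
#' @return A [landscape()].
#' @export
load_landscape <- function(path, sidecar_path = NULL) {
  if (is.null(sidecar_path)) sidecar_path <- sidecar_name(path)
  for (p in c(path, sidecar_path))
    if (!file.exists(p)) stop("load_landscape: file not found: ", p, call. = FALSE)
  main <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(mutation_codes = "character"))
  miss <- setdiff(landscape_cols, names(main))
  if (length(miss))
    stop("load_landscape: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  side <- utils::read.csv(sidecar_path, stringsAsFactors = FALSE)
  smiss <- setdiff(c("variant", "draw", "log_g0", "log_ginf", "log_ec50", "n"),
                   names(side))
  if (length(smiss))
    stop("load_landscape: sidecar missing columns: ",
         paste(smiss, collapse = ", "), call. = FALSE)
  num <- as.matrix(main[, c("log_g0", "log_ginf", "log_ec50", "n")])
  badnum <- which(!apply(is.finite(num), 1L, all))
  if (length(badnum))
    stop("load_landscape: non-finite parameters at row(s): ",
         paste(badnum, collapse = ", "), call. = FALSE)
  gts <- vector("list", nrow(main))
  for (i in seq_len(nrow(main))) {
    gts[[i]] <- tryCatch(
      genotype(strsplit(main$mutation_codes[i], ",", fixed = TRUE)[[1]]),
      error = function(e)
        stop("load_landscape: row ", i, ": ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(main$quality)) main$quality <- 1
  bysamp <- split(side, side$variant)
  records <- vector("list", nrow(main))
  for (i in seq_len(nrow(main))) {
    v <- main$variant[i]
    sm <- bysamp[[as.character(v)]]
    if (is.null(sm))
      stop("load_landscape: no posterior samples for variant ", v, call. = FALSE)
    sm <- sm[order(sm$draw), c("log_g0", "log_ginf", "log_ec50", "n")]
    records[[i]] <- variant_record(gts[[i]], hill_posterior(as.matrix(sm)),
                                   quality = main$quality[i], id = v)
  }
  landscape(records)
}

#' Filter a landscape by a predicate on posterior summaries
#'
#' @param x A [landscape()].
#' @param predicate Function receiving the landscape summary data frame
#'   (posterior medians `g0`, `ginf`, `ec50`, `n` on natural scales, plus
#'   `n_mut`, `quality`, `inverted`) and returning a logical vector.
#' @return List of the matching [variant_record()]s, in landscape order.
#' @examples
#' \donttest{
#' ls <- simulate_landscape(simulate_library(50, seed = 1), seed = 1)
#' mid <- query_landscape(ls, function(s) s$ec50 >= 90 & s$ec50 <= 110)
#' }
#' @export
query_landscape <- function(x, predicate) {
  stopifnot(inherits(x, "landscape"), is.function(predicate))
  keep <- predicate(x$summary)
  if (!is.logical(keep) || length(keep) != length(x$records))
    stop("query_landscape: predicate must return one logical per record",
         call. = FALSE)
  keep[is.na(keep)] <- FALSE
  x$records[keep]
}

#' Restrict a landscape to single-mutant variants
#'
#' @param x A [landscape()].
#' @return A [landscape()] containing only records with exactly one
#'   missense mutation; the vocabulary is recomputed.
#' @export
single_mutant_restriction <- function(x) {
  stopifnot(inherits(x, "landscape"))
  landscape(x$records[x$summary$n_mut == 1L])
}
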