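#' Ranked contact predictions and consensus contact sets
#'
#' Contact predictors emit ranked residue-pair lists in the CASP RR dialect
#' (`i j d_lo d_hi confidence`, or the short `i j confidence` form).
#' Predictors are grouped into four accuracy tiers; the consensus set unions
#' each predictor's tier-dependent top-ranked pairs.
#'
#' @name contact_consensus
NULL

#' Default accuracy tier of the named contact predictors
#'
#' Maps predictor names (case-insensitive) to the four accuracy categories.
#' Unknown predictors must be given an explicit category.
#'
#' @return named character vector: predictor -> category.
#' @export
default_predictor_categories <- function() {
  c(nebcon = "very_high", respre = "very_high", deepplm = "very_high",
    deepcov = "high", deepcontact = "high", dncon2 = "high",
    metapsicov2 = "medium",
    gremlin = "low", ccmpred = "low", freecontact = "low")
}

predictor_categories <- c("very_high", "high", "medium", "low")

#' Construct a predictor output object
#'
#' @param predictor_name identifier.
#' @param pairs data.frame with columns `i`, `j`, `confidence`.
#' @param category accuracy tier; looked up from
#'   [default_predictor_categories()] when `NULL`.
#' @param L sequence length (upper bound for residue indices).
#' @return a `PredictorOutput`: pairs normalized to `i < j`, sorted by
#'   confidence descending with ties broken by `(i, j)` ascending.
#' @export
predictor_output <- function(predictor_name, pairs, category = NULL, L = NULL) {
  if (is.null(category)) {
    category <- default_predictor_categories()[tolower(predictor_name)]
    if (is.na(category)) {
      cf_abort("cf_unknown_predictor_error",
               "unknown predictor '%s': supply an explicit category",
               predictor_name)
    }
  }
  category <- match.arg(category, predictor_categories)
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("i", "j", "confidence") %in% names(pairs)))
  i <- pmin(pairs$i, pairs$j)
  j <- pmax(pairs$i, pairs$j)
  if (any(i == j)) {
    cf_abort("cf_malformed_rr_error", "self-pair (i == j) in contact list")
  }
  if (!is.null(L) && (any(i < 1) || any(j > L))) {
    cf_abort("cf_index_range_error",
             "contact index outside [1, %d]", L)
  }
  if (any(pairs$confidence < 0 | pairs$confidence > 1)) {
    cf_abort("cf_malformed_rr_error", "confidence outside [0, 1]")
  }
  ord <- order(-pairs$confidence, i, j)
  df <- data.frame(i = as.integer(i[ord]), j = as.integer(j[ord]),
                   confidence = as.numeric(pairs$confidence[ord]))
  # duplicate pairs within one predictor: keep highest-confidence record
  df <- df[!duplicated(df[, c("i", "j")]), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(predictor_name = predictor_name, category = category,
                 pairs = df),
            class = "PredictorOutput")
}

#' Read a CASP-RR-style contact file
#'
#' Accepts 5-column (`i j d_lo d_hi conf`) and 3-column (`i j conf`) data
#' lines; `PFRMAT`, `TARGET`, `MODEL`, `END` and comment lines are skipped.
#'
#' @param path file path.
#' @param L sequence length; indices must fall in `[1, L]`.
#' @param predictor_name identifier (defaults to the file base name).
#' @param category accuracy tier; see [predictor_output()].
#' @return a `PredictorOutput`.
#' @export
read_rr <- function(path, L, predictor_name = NULL, category = NULL) {
  if (!file.exists(path)) {
    cf_abort("cf_unreadable_error", "cannot read contact file '%s'", path)
  }
  predictor_name <- predictor_name %||%
    sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  skip <- grepl("^(PFRMAT|TARGET|AUTHOR|METHOD|MODEL|REMARK|END|#)", lines)
  # a leading plain-sequence line (letters only) is also metadata
  skip <- skip | grepl("^[A-Za-z]+$", lines)
  lines <- lines[!skip]
  if (length(lines) == 0L) {
    cf_abort("cf_malformed_rr_error", "no contact records in '%s'", path)
  }
  fields <- strsplit(lines, "\\s+")
  nfield <- lengths(fields)
  if (!all(nfield %in% c(3L, 5L))) {
    cf_abort("cf_malformed_rr_error",
             "malformed RR line: '%s'", lines[which(!nfield %in% c(3L, 5L))[1]])
  }
  parse_num <- function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) cf_abort("cf_malformed_rr_error", "non-numeric RR field")
    v
  }
  i <- parse_num(vapply(fields, `[[`, "", 1L))
  j <- parse_num(vapply(fields, `[[`, "", 2L))
  conf <- parse_num(mapply(function(f, n) f[[n]], fields, nfield))
  if (any(i != round(i) | j != round(j))) {
    cf_abort("cf_malformed_rr_error", "non-integer residue index")
  }
  predictor_output(predictor_name,
                   data.frame(i = as.integer(i), j = as.integer(j),
                              confidence = conf),
                   category = category, L = L)
}

#' Write a contact set in RR format
#'
#' @param x a `PredictorOutput` or `ConsensusContactSet`.
#' @param path output file path.
#' @param target optional TARGET header value.
#' @return `path`, invisibly.
#' @export
write_rr <- function(x, path, target = NULL) {
  df <- if (inherits(x, "ConsensusContactSet")) {
    data.frame(i = x$contacts$i, j = x$contacts$j, conf = x$contacts$u)
  } else if (inherits(x, "PredictorOutput")) {
    data.frame(i = x$pairs$i, j = x$pairs$j, conf = x$pairs$confidence)
  } else {
    cf_abort("cf_domain_error", "cannot write object of class %s as RR",
             class(x)[1])
  }
  hdr <- c("PFRMAT RR", if (!is.null(target)) paste("TARGET", target))
  body <- sprintf("%d %d 0 8 %.6f", df$i, df$j, df$conf)
  writeLines(c(hdr, body, "END"), path)
  invisible(path)
}

#' Tier-dependent number of consensus contacts
#'
#' Top-ranked list size per accuracy tier: L, L/2, L/4.5 and L/7.5 for the
#' very-high, high, medium and low tiers, rounded half-up with a floor of 1.
#'
#' @param category accuracy tier.
#' @param L sequence length (>= 1).
#' @return integer count.
#' @export
top_count <- function(category, L) {
  category <- match.arg(category, predictor_categories)
  stopifnot(L >= 1)
  div <- c(very_high = 1, high = 2, medium = 4.5, low = 7.5)[[category]]
  max(1L, as.integer(round_half_up(L / div)))
}

#' Default consensus selection scheme
#'
#' Both branches of the alignment-depth switch (`nf < nf_switch` versus
#' `>= nf_switch`) default to the same fraction list; they are exposed
#' separately so an asymmetric scheme can be configured.
#'
#' @param nf_switch alignment-depth switch point (default 50).
#' @return a `CategoryScheme` list.
#' @export
category_scheme <- function(nf_switch = 50) {
  fracs <- c(very_high = 1, high = 2, medium = 4.5, low = 7.5)
  structure(list(low_nf = fracs, high_nf = fracs, nf_switch = nf_switch),
            class = "CategoryScheme")
}

separation_class <- function(i, j) {
  sep <- abs(j - i)
  ifelse(sep > 24, "long", ifelse(sep >= 12, "medium", "short"))
}

new_consensus_set <- function(df, L) {
  ord <- order(-df$u, df$i, df$j)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(contacts = df, L = as.integer(L)),
            class = "ConsensusContactSet")
}

#' Build the consensus contact set from several predictor outputs
#'
#' Each predictor's ranked list is truncated to its tier-dependent
#' [top_count()]; the truncated lists are unioned and each surviving pair's
#' restraint weight `U_ij` is the mean confidence over the predictors that
#' report it. Pairs are annotated with a sequence-separation class
#' (short 1-11, medium 12-24, long > 24) and ordered by `U_ij` descending.
#'
#' @param outputs list of `PredictorOutput` objects.
#' @param L sequence length.
#' @param nf effective sequence count of the family's MSA (selects the
#'   scheme branch).
#' @param scheme a [category_scheme()].
#' @return a `ConsensusContactSet`: data.frame `contacts` with columns
#'   `i`, `j`, `u`, `sep_class`, plus the length `L`.
#' @export
build_consensus <- function(outputs, L, nf = Inf, scheme = category_scheme()) {
  if (length(outputs) == 0L) {
    cf_abort("cf_domain_error", "no predictor outputs supplied")
  }
  stopifnot(all(vapply(outputs, inherits, TRUE, "PredictorOutput")))
  fracs <- if (nf < scheme$nf_switch) scheme$low_nf else scheme$high_nf
  truncated <- lapply(outputs, function(po) {
    k <- max(1L, as.integer(round_half_up(L / fracs[[po$category]])))
    utils::head(po$pairs, k)
  })
  all_pairs <- do.call(rbind, truncated)
  key <- paste(all_pairs$i, all_pairs$j)
  u <- tapply(all_pairs$confidence, key, mean)
  ij <- do.call(rbind, strsplit(names(u), " ", fixed = TRUE))
  df <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                   u = as.numeric(u))
  df$sep_class <- separation_class(df$i, df$j)
  new_consensus_set(df, L)
}

#' @export
print.ConsensusContactSet <- function(x, ...) {
  tab <- table(factor(x$contacts$sep_class,
                      levels = c("short", "medium", "long")))
  cat(sprintf("ConsensusContactSet: %d contacts (L = %d; short %d, medium %d, long %d)\n",
              nrow(x$contacts), x$L, tab[["short"]], tab[["medium"]],
              tab[["long"]]))
  invisible(x)
}

#' Top long-range contacts of a consensus set
#'
#' Long-range means sequence separation strictly greater than 24. The
#' surviving contacts are truncated to the `top` highest-weight pairs.
#'
#' @param cs a `ConsensusContactSet`.
#' @param top maximum number of contacts returned (>= 0).
#' @return a `ConsensusContactSet` restricted to long-range pairs.
#' @export
long_range_subset <- function(cs, top = cs$L) {
  stopifnot(inherits(cs, "ConsensusContactSet"), top >= 0)
  df <- cs$contacts[abs(cs$contacts$j - cs$contacts$i) > 24, , drop = FALSE]
  df <- df[order(-df$u, df$i, df$j), , drop = FALSE]
  new_consensus_set(utils::head(df, top), cs$L)
}
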