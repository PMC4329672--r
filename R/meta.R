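# Meta-analysis operations over curated variant tables.

#' Mutation spectrum by site position, versus average information
#'
#' Histogram of deleterious variants per model offset, and the Pearson
#' correlation of those counts with the model's per-position average
#' information profile. A strong correlation indicates that susceptibility
#' to deleterious mutation at a position tracks its conservation within the
#' site.
#'
#' @param variantTable data.frame with columns \code{offset} (model offsets)
#'   and \code{deleterious} (logical); rows with \code{deleterious = FALSE}
#'   are ignored for the histogram.
#' @param model the \code{\linkS4class{InfoModel}} whose window the offsets
#'   refer to.
#' @return list with \code{counts} (named integer vector over all model
#'   offsets), \code{profile} (average information per offset, bits) and
#'   \code{r} (Pearson correlation; \code{NA} when fewer than 3 distinct
#'   offsets carry variants).
#' @export
positionSpectrum <- function(variantTable, model) {
  stopifnot(is(model, "InfoModel"))
  offs <- as.integer(colnames(model@weights))
  if (!all(c("offset", "deleterious") %in% names(variantTable)))
    stop("variantTable needs columns 'offset' and 'deleterious'")
  bad <- setdiff(unique(variantTable$offset), offs)
  if (length(bad))
    stop("offsets outside the model window: ", paste(bad, collapse = ", "))
  del <- variantTable[variantTable$deleterious, , drop = FALSE]
  counts <- vapply(offs, function(o) sum(del$offset == o), 0L)
  names(counts) <- as.character(offs)
  profile <- averageInformation(model)$profile
  r <- if (length(unique(del$offset)) < 3L) NA_real_
       else stats::cor(counts, profile)
  list(counts = counts, profile = profile, r = r)
}

CONCORDANCE_FIELDS <- c("predicted", "observed_splicing_loss",
                        "observed_residual_splicing", "rtpcr_heterozygote",
                        "stronger_cryptic_activated", "cryptic_observed",
                        "cryptic_top_ranked", "wildtype_level",
                        "binding_concordant", "uninformative")

#' Concordance of predictions with experimental validation
#'
#' Labels each prediction/validation record concordant, discordant or
#' partially concordant under the criteria used for the meta-analysis of
#' validated splicing variants:
#' \itemize{
#' \item a. predicted abolished and splicing abolished with no residual
#'   splicing; residual signal is excused when mutant and wild-type alleles
#'   could not be discriminated (RT-PCR of a heterozygote);
#' \item b. predicted leaky and residual normal splicing observed, excusing
#'   cases where a much stronger cryptic site was activated;
#' \item c. predicted natural-site strengthening with normal or increased
#'   wild-type isoform levels;
#' \item d. predicted cryptic activation (with natural-site weakening)
#'   observed experimentally -- partial when the observed cryptic site was
#'   predicted but not ranked the predominant isoform;
#' \item e. predicted regulatory-site change consistent with a direct
#'   binding/splicing assay.
#' }
#' Records flagged uninformative (or missing a field the matching criterion
#' needs) are excluded from the denominator. Partially concordant records
#' count toward the concordant total, as in the source criteria.
#'
#' @param records data.frame; required column \code{predicted} with values
#'   in \code{abolished}, \code{leaky}, \code{strengthened},
#'   \code{cryptic}, \code{regulatory}; the remaining logical columns are
#'   consulted per criterion (see above), and \code{uninformative} excludes
#'   a record outright.
#' @return list with \code{labels} (character per record),
#'   \code{nConcordant} (includes partial), \code{nPartial},
#'   \code{nInformative} and \code{percentConcordant}.
#' @export
assessConcordance <- function(records) {
  if (!"predicted" %in% names(records))
    stop("records need a 'predicted' column")
  getl <- function(col, i) {
    if (!col %in% names(records)) return(NA)
    records[[col]][i]
  }
  labels <- vapply(seq_len(nrow(records)), function(i) {
    if (isTRUE(getl("uninformative", i))) return("uninformative")
    p <- records$predicted[i]
    switch(p,
      abolished = {
        loss <- getl("observed_splicing_loss", i)
        resid <- getl("observed_residual_splicing", i)
        if (is.na(loss)) return("uninformative")
        if (loss && (!isTRUE(resid) || isTRUE(getl("rtpcr_heterozygote", i))))
          "concordant" else "discordant"
      },
      leaky = {
        resid <- getl("observed_residual_splicing", i)
        if (is.na(resid)) return("uninformative")
        if (resid || isTRUE(getl("stronger_cryptic_activated", i)))
          "concordant" else "discordant"
      },
      strengthened = {
        wt <- getl("wildtype_level", i)
        if (is.na(wt)) return("uninformative")
        if (wt %in% c("normal", "increased")) "concordant" else "discordant"
      },
      cryptic = {
        obs <- getl("cryptic_observed", i)
        if (is.na(obs)) return("uninformative")
        if (!obs) return("discordant")
        if (isTRUE(getl("cryptic_top_ranked", i))) "concordant" else "partial"
      },
      regulatory = {
        bc <- getl("binding_concordant", i)
        if (is.na(bc)) return("uninformative")
        if (bc) "concordant" else "discordant"
      },
      stop("unknown predicted category: ", p)
    )
  }, "")
  informative <- labels != "uninformative"
  nConc <- sum(labels %in% c("concordant", "partial"))
  list(labels = labels,
       nConcordant = nConc,
       nPartial = sum(labels == "partial"),
       nInformative = sum(informative),
       percentConcordant = if (any(informative))
         100 * nConc / sum(informative) else NA_real_)
}
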