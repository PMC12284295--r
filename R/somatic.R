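#' Somatic allele frequency of a call
#'
#' The fraction of reads supporting the alternate allele,
#' `ad_alt / (ad_ref + ad_alt)`, defined only for calls with a total allele
#' support of at least `min_support` reads (default 10).
#'
#' @param ad_ref,ad_alt Reference / alternate allele depths (vectorised).
#' @param min_support Minimum total allele support.
#' @return Allele frequency in `[0, 1]`, `NA` below the support gate.
#' @examples
#' allele_frequency(5, 5)    # 0.5
#' allele_frequency(21, 4)   # 0.16
#' allele_frequency(6, 3)    # NA: only 9 supporting reads
#' @export
allele_frequency <- function(ad_ref, ad_alt, min_support = 10) {
  tot <- ad_ref + ad_alt
  ifelse(!is.na(tot) & tot >= min_support, ad_alt / tot, NA_real_)
}

#' Allele-frequency matrix of a variant table
#'
#' @param x A `variant_table`.
#' @param min_support Minimum total allele support per call.
#' @return sites x samples matrix of allele frequencies (`NA` where
#'   undefined).
#' @export
af_matrix <- function(x, min_support = 10) {
  stopifnot(inherits(x, "variant_table"))
  matrix(allele_frequency(x$ad_ref, x$ad_alt, min_support),
         nrow(x$sites), ncol(x$gt), dimnames = dimnames(x$gt))
}

## carrier = non-hom-ref called genotype (optionally het only)
.carrier_matrix <- function(x, carriers = c("any", "het")) {
  carriers <- match.arg(carriers)
  cm <- if (carriers == "het") x$gt == 1 else x$gt >= 1
  cm[is.na(cm)] <- FALSE
  cm
}

#' Classify sites as shared or substrain-specific
#'
#' A sample carries a site when its called genotype is non-hom-ref (or
#' strictly heterozygous with `carriers = "het"`).  A site is `shared` when
#' at least one individual of each group carries it, `<group>-specific` when
#' only one group has carriers, and `absent` otherwise.  Bottleneck (`FSB`)
#' samples can be appended to the FS side via `fsb_with`.
#'
#' @param x A `variant_table`.
#' @param pedigree Sample metadata with `substrain`.
#' @param groups Length-2 character vector of the substrains to contrast.
#' @param fsb_with Optionally, the group (`"FS"` or `"PH"`) to which FSB
#'   samples are added; `NULL` leaves them out.
#' @param carriers `"any"` (het or hom-alt) or `"het"`.
#' @return factor per site with levels `shared`, `<g1>-specific`,
#'   `<g2>-specific`, `absent`.
#' @export
classify_specificity <- function(x, pedigree, groups = c("FS", "PH"),
                                 fsb_with = NULL, carriers = "any") {
  stopifnot(inherits(x, "variant_table"), length(groups) == 2)
  unknown <- setdiff(unique(pedigree$substrain), c("FS", "PH", "FSB"))
  if (length(unknown))
    stop("unknown substrain label(s): ", paste(unknown, collapse = ", "))
  sets <- lapply(groups, function(g)
    pedigree$sample_id[pedigree$substrain == g])
  names(sets) <- groups
  if (!is.null(fsb_with))
    sets[[fsb_with]] <- c(sets[[fsb_with]],
                          pedigree$sample_id[pedigree$substrain == "FSB"])
  sets <- lapply(sets, intersect, sample_names(x))
  cm <- .carrier_matrix(x, carriers)
  in1 <- rowSums(cm[, sets[[1]], drop = FALSE]) > 0
  in2 <- rowSums(cm[, sets[[2]], drop = FALSE]) > 0
  lv <- c("shared", paste0(groups[1], "-specific"),
          paste0(groups[2], "-specific"), "absent")
  cls <- ifelse(in1 & in2, lv[1],
                ifelse(in1, lv[2], ifelse(in2, lv[3], lv[4])))
  factor(cls, levels = lv)
}

#' Allelic-imbalance summary by specificity class
#'
#' Pools the allele frequencies of all carrier (site, sample) records with
#' defined AF, per specificity class within each group's samples, and
#' returns both the per-class means and the per-SNP-record vectors consumed
#' by (delegated) Wilcoxon tests.
#'
#' @param x A `variant_table`.
#' @param classes Site classes from [classify_specificity()].
#' @param pedigree Sample metadata.
#' @param groups The two substrains contrasted in `classes`.
#' @param fsb_with As in [classify_specificity()]; must match.
#' @param min_support Minimum allele support for a defined AF.
#' @return List with `summary` (data.frame `group, class, mean_af, n`) and
#'   `records` (named list of AF vectors, one per group x class).
#' @export
imbalance_summary <- function(x, classes, pedigree, groups = c("FS", "PH"),
                              fsb_with = NULL, min_support = 10) {
  af <- af_matrix(x, min_support)
  cm <- .carrier_matrix(x, "any")
  sets <- lapply(groups, function(g)
    pedigree$sample_id[pedigree$substrain == g])
  names(sets) <- groups
  if (!is.null(fsb_with))
    sets[[fsb_with]] <- c(sets[[fsb_with]],
                          pedigree$sample_id[pedigree$substrain == "FSB"])
  sets <- lapply(sets, intersect, sample_names(x))
  rows <- list()
  records <- list()
  for (g in groups) {
    for (cl in c("shared", paste0(g, "-specific"))) {
      sel_sites <- classes == cl
      sub_af <- af[sel_sites, sets[[g]], drop = FALSE]
      sub_cm <- cm[sel_sites, sets[[g]], drop = FALSE]
      vals <- sub_af[sub_cm & !is.na(sub_af)]
      key <- paste0(g, ".", cl)
      records[[key]] <- vals
      rows[[key]] <- data.frame(group = g, class = cl,
                                mean_af = if (length(vals)) mean(vals) else NA_real_,
                                n = length(vals), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(summary = out, records = records)
}

#' Ancestral group-specific sites
#'
#' The subset of group-specific sites carried by every individual of that
#' group -- candidate ancestral variants, used to show that long-established
#' specific variants lose their allelic imbalance.
#'
#' @param x A `variant_table`.
#' @param classes Site classes from [classify_specificity()].
#' @param pedigree Sample metadata.
#' @param group The group (substrain) whose specific sites are screened.
#' @param include_fsb Also require/allow FSB samples on the FS side.
#' @param carriers `"any"` or `"het"`.
#' @return Logical vector over sites: ancestral group-specific or not.
#' @export
ancestral_specific_subset <- function(x, classes, pedigree, group = "FS",
                                      include_fsb = FALSE, carriers = "any") {
  samp <- pedigree$sample_id[pedigree$substrain == group]
  if (include_fsb && group == "FS")
    samp <- c(samp, pedigree$sample_id[pedigree$substrain == "FSB"])
  samp <- intersect(samp, sample_names(x))
  cm <- .carrier_matrix(x, carriers)
  all_carry <- rowSums(cm[, samp, drop = FALSE]) == length(samp)
  classes == paste0(group, "-specific") & all_carry
}
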