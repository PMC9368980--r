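#' Parse ACMG evidence codes
#'
#' Maps each evidence code to its category and strength from the code
#' prefix: PVS (pathogenic very strong), PS (strong), PM (moderate), PP
#' (supporting), BA (benign stand-alone), BS (strong), BP (supporting).
#' The deprecated reputable-source codes PP5/BP6 are accepted as ordinary
#' supporting codes.
#'
#' @param codes Character vector of codes, e.g. `c("PS4", "PM2", "BP4")`.
#' @return A tibble: `code`, `category`, `strength`.
#' @export
acmg_criteria <- function(codes) {
  codes <- unique(as.character(codes))
  prefix <- stringr::str_extract(toupper(codes), "^(PVS|PS|PM|PP|BA|BS|BP)")
  valid <- !is.na(prefix) &
    grepl("^(PVS|PS|PM|PP|BA|BS|BP)[0-9]+$", toupper(codes))
  if (any(!valid)) {
    abort(paste("unknown ACMG code(s):",
                paste(codes[!valid], collapse = ", ")))
  }
  tibble(
    code = toupper(codes),
    category = ifelse(prefix %in% c("PVS", "PS", "PM", "PP"),
                      "pathogenic", "benign"),
    strength = unname(c(PVS = "very_strong", PS = "strong", PM = "moderate",
                        PP = "supporting", BA = "stand_alone", BS = "strong",
                        BP = "supporting")[prefix])
  )
}

#' Combine ACMG criteria into a five-tier class
#'
#' Applies the standard ACMG/AMP combining rules to a set of evidence
#' codes and returns the class on the 1-5 scale (1 benign, 2 likely
#' benign, 3 uncertain significance, 4 likely pathogenic, 5 pathogenic).
#'
#' Pathogenic: 1 PVS with (>=1 PS, >=2 PM, 1 PM + 1 PP, or >=2 PP);
#' >=2 PS; or 1 PS with (>=3 PM, 2 PM + >=2 PP, or 1 PM + >=4 PP).
#' Likely pathogenic: 1 PVS + 1 PM; 1 PS + 1-2 PM; 1 PS + >=2 PP;
#' >=3 PM; 2 PM + >=2 PP; or 1 PM + >=4 PP.
#' Benign: BA1, or >=2 BS. Likely benign: 1 BS + 1 BP, or >=2 BP.
#'
#' Two deliberate deviations from a strict reading: (i) benign
#' *supporting* codes (BP) do not veto an otherwise met pathogenic
#' combination (stand-alone/strong benign evidence still forces class 3 by
#' conflict); (ii) the exact criteria set \{PS4, PM2\} — case-enrichment
#' plus population absence and nothing else — stays class 3, a
#' conservatism for cohort-derived PS4 evidence.
#'
#' @param codes Character vector of ACMG codes (may be empty).
#' @return Integer class code in 1..5.
#' @export
combine_criteria <- function(codes) {
  cr <- acmg_criteria(codes)
  n <- function(cat, str) sum(cr$category == cat & cr$strength == str)
  pvs <- n("pathogenic", "very_strong"); ps <- n("pathogenic", "strong")
  pm <- n("pathogenic", "moderate"); pp <- n("pathogenic", "supporting")
  ba <- n("benign", "stand_alone"); bs <- n("benign", "strong")
  bp <- n("benign", "supporting")

  pathogenic <- (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm == 1 && pp == 1) ||
                                pp >= 2)) ||
    ps >= 2 ||
    (ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4)))
  likely_path <- (pvs >= 1 && pm >= 1) ||
    (ps == 1 && pm >= 1 && pm <= 2) ||
    (ps == 1 && pp >= 2) ||
    pm >= 3 || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4)
  benign <- ba >= 1 || bs >= 2
  likely_ben <- (bs == 1 && bp >= 1) || bp >= 2

  path_class <- if (pathogenic) 5L else if (likely_path) 4L else NA_integer_
  strong_benign_evidence <- ba >= 1 || bs >= 1

  if (setequal(cr$code, c("PS4", "PM2"))) return(3L)
  if (!is.na(path_class)) {
    if (strong_benign_evidence) return(3L)  # genuine conflict
    return(path_class)
  }
  if (benign) return(1L)
  if (likely_ben) return(2L)
  3L
}

#' Reclassify a VUS by injecting the PS4 criterion
#'
#' PS4 states that the prevalence of the variant in affected individuals is
#' significantly increased compared with controls. Here the evidence comes
#' from the cohort database: when the variant's case-versus-pseudocontrol
#' `log2fc` is at least `fc_threshold`, PS4 (at strong) is added to the
#' prior criteria and the ACMG class recombined; below the threshold the
#' profile is unchanged. A variant counts as reclassified when it moves
#' from class 3 to class 4 or 5.
#'
#' @param criteria Character vector of prior ACMG codes.
#' @param log2fc The variant's log2 fold change against pseudocontrols.
#' @param fc_threshold Minimum log2 fold change for PS4 (default 1.5).
#' @return A one-row tibble: `old_class`, `new_class`, `ps4_applied`,
#'   `reclassified`.
#' @export
reclassify_with_ps4 <- function(criteria, log2fc, fc_threshold = 1.5) {
  if (is.na(log2fc)) abort("log2fc must be defined for PS4 eligibility")
  if ("PS4" %in% toupper(criteria)) {
    warn("PS4 already present in prior criteria; recombining without duplication")
  }
  old <- combine_criteria(criteria)
  apply_ps4 <- log2fc >= fc_threshold
  new <- if (apply_ps4) combine_criteria(union(toupper(criteria), "PS4")) else old
  tibble(old_class = old, new_class = new, ps4_applied = apply_ps4,
         reclassified = old == 3L & new >= 4L)
}

#' Batch PS4 reclassification of a curated VUS table
#'
#' @param vus_tbl Tibble from [read_vus_profiles()] (columns `gene`,
#'   `log2fc`, `criteria` list-column; other columns carried through).
#' @param fc_threshold Minimum log2 fold change for PS4 (default 1.5).
#' @return An object of class `vus_reclassification`: the per-row table
#'   plus outcome counts; see [tidy()] and [glance()].
#' @export
batch_reclassify <- function(vus_tbl, fc_threshold = 1.5) {
  if (nrow(vus_tbl) == 0) {
    res <- vus_tbl %>% mutate(old_class = integer(), new_class = integer(),
                              ps4_applied = logical(),
                              reclassified = logical())
  } else {
    res <- vus_tbl %>%
      mutate(purrr::map2_dfr(.data$criteria, .data$log2fc,
                             reclassify_with_ps4,
                             fc_threshold = fc_threshold))
  }
  structure(list(results = res,
                 n = nrow(res),
                 n_ps4 = sum(res$ps4_applied),
                 n_reclassified = sum(res$reclassified),
                 fc_threshold = fc_threshold),
            class = "vus_reclassification")
}

#' @export
print.vus_reclassification <- function(x, ...) {
  cat("<vus_reclassification> ", x$n, " profiles, PS4 applied to ", x$n_ps4,
      ", reclassified ", x$n_reclassified, "\n", sep = "")
  invisible(x)
}

#' @rdname batch_reclassify
#' @param x A `vus_reclassification` object.
#' @param ... Unused.
#' @export
tidy.vus_reclassification <- function(x, ...) {
  x$results %>%
    mutate(criteria = purrr::map_chr(.data$criteria, paste, collapse = ","))
}

#' @rdname batch_reclassify
#' @export
glance.vus_reclassification <- function(x, ...) {
  tibble(n = x$n, n_ps4_applied = x$n_ps4,
         n_reclassified = x$n_reclassified,
         prop_reclassified = ifelse(x$n > 0, x$n_reclassified / x$n, NA_real_),
         fc_threshold = x$fc_threshold)
}

#' Bundled curated VUS evidence table
#'
#' A small curated set of variants of uncertain significance from an
#' inherited retinal dystrophy cohort reanalysis, with the prior ACMG
#' evidence codes asserted for each variant and its case-versus-
#' pseudocontrol log2 fold change; the worked example for
#' [batch_reclassify()].
#'
#' @return A tibble as from [read_vus_profiles()].
#' @export
curated_vus_example <- function() {
  read_vus_profiles(system.file("extdata", "curated_vus.tsv",
                                package = "cohortAF", mustWork = TRUE))
}
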