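ACMG_PREFIXES <- c("PVS", "PS", "PM", "PP", "BA", "BS", "BP")
ACMG_GRAMMAR <- "^(PVS|PS|PM|PP|BA|BS|BP)[0-9]+$"
VERDICT_LEVELS <- c("benign", "likely_benign", "vus", "likely_pathogenic",
                    "pathogenic")

#' Parse a comma-separated list of ACMG evidence codes
#'
#' Tokens must match the ACMG grammar `(PVS|PS|PM|PP|BA|BS|BP)<digit(s)>`.
#' Whitespace is tolerated, duplicates collapse, and the result is a
#' canonical upper-case set. With `lenient = TRUE`, tokens whose first two
#' letters are a transposed valid prefix (published tables occasionally
#' contain typos such as `"PB4"` for `"BP4"`) are auto-corrected, each
#' correction reported via a message.
#'
#' @param text A single string such as `"PVS1, PM2"`; `""`/`NA` give an
#'   empty set.
#' @param lenient Auto-correct transposed two-letter prefixes.
#' @return Character vector of canonical codes (sorted, unique).
#' @examples
#' parse_evidence_codes("PVS1,PM2")
#' parse_evidence_codes("BS1, BS2, BP4, BP1")
#' parse_evidence_codes("PB4,PM2", lenient = TRUE)  # PB4 -> BP4
#' @export
parse_evidence_codes <- function(text, lenient = FALSE) {
  if (length(text) != 1L) stop_input("parse_evidence_codes() expects one string")
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  toks <- toupper(trimws(strsplit(text, ",", fixed = TRUE)[[1]]))
  toks <- toks[nzchar(toks)]
  fix_one <- function(tok) {
    if (grepl(ACMG_GRAMMAR, tok)) return(tok)
    if (lenient && grepl("^[A-Z]{2}[0-9]+$", tok)) {
      swapped <- paste0(substr(tok, 2, 2), substr(tok, 1, 1),
                        substring(tok, 3))
      if (grepl(ACMG_GRAMMAR, swapped)) {
        inform(sprintf("ACMG token '%s' auto-corrected to '%s'", tok, swapped))
        return(swapped)
      }
    }
    stop_format(sprintf("invalid ACMG evidence code '%s'", tok))
  }
  sort(unique(vapply(toks, fix_one, character(1), USE.NAMES = FALSE)))
}

#' Count evidence codes by strength category
#'
#' @param codes Character vector of canonical codes.
#' @return Named integer vector over `PVS, PS, PM, PP, BA, BS, BP`.
#' @export
acmg_strength_counts <- function(codes) {
  bad <- !grepl(ACMG_GRAMMAR, codes)
  if (any(bad)) {
    stop_format(sprintf("invalid ACMG evidence code '%s'", codes[bad][1L]))
  }
  prefix <- sub("[0-9]+$", "", codes)
  counts <- table(factor(prefix, levels = ACMG_PREFIXES))
  setNames(as.integer(counts), ACMG_PREFIXES)
}

#' Combine ACMG evidence codes into a five-tier verdict
#'
#' Implements the canonical 2015 ACMG/AMP combining rules. Pathogenic: one
#' very-strong plus (one strong, two moderate, one moderate + one
#' supporting, or two supporting); two strong; or one strong plus (three
#' moderate, two moderate + two supporting, or one moderate + four
#' supporting). Likely pathogenic: one very-strong + one moderate; one
#' strong + one or two moderate; one strong + two supporting; three
#' moderate; two moderate + two supporting; or one moderate + four
#' supporting. Benign: stand-alone `BA1` or two strong-benign. Likely
#' benign: one strong-benign + one supporting-benign, or two
#' supporting-benign. When a pathogenic-side rule and a benign-side rule
#' fire simultaneously the evidence is contradictory and the verdict is
#' `vus`; so is any code set satisfying no rule.
#'
#' @param codes Character vector of canonical codes (see
#'   [parse_evidence_codes()]).
#' @return One of `"pathogenic"`, `"likely_pathogenic"`, `"vus"`,
#'   `"likely_benign"`, `"benign"`.
#' @examples
#' combine_acmg(c("PVS1", "PM2"))          # likely_pathogenic
#' combine_acmg(c("PVS1", "PP5", "PM2"))   # pathogenic
#' combine_acmg("PM2")                     # vus
#' combine_acmg("BA1")                     # benign
#' @export
combine_acmg <- function(codes) {
  k <- acmg_strength_counts(codes)
  pvs <- k[["PVS"]]; ps <- k[["PS"]]; pm <- k[["PM"]]; pp <- k[["PP"]]
  ba <- k[["BA"]]; bs <- k[["BS"]]; bp <- k[["BP"]]

  pathogenic <-
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm >= 1 && pp >= 1) || pp >= 2)) ||
    ps >= 2 ||
    (ps >= 1 && (pm >= 3 || (pm >= 2 && pp >= 2) || (pm >= 1 && pp >= 4)))
  likely_pathogenic <- !pathogenic && (
    (pvs >= 1 && pm >= 1) ||
    (ps >= 1 && pm >= 1) ||
    (ps >= 1 && pp >= 2) ||
    pm >= 3 ||
    (pm >= 2 && pp >= 2) ||
    (pm >= 1 && pp >= 4))
  benign <- ba >= 1 || bs >= 2
  likely_benign <- !benign && ((bs >= 1 && bp >= 1) || bp >= 2)

  path_side <- pathogenic || likely_pathogenic
  benign_side <- benign || likely_benign
  if (path_side && benign_side) return("vus")
  if (pathogenic) return("pathogenic")
  if (likely_pathogenic) return("likely_pathogenic")
  if (benign) return("benign")
  if (likely_benign) return("likely_benign")
  "vus"
}

# Normalize printed verdict strings ("Likely Pathogenic", "VUS", and the
# occasional "Likey Benign" misspelling) to the five canonical levels.
normalize_verdict <- function(x) {
  x <- absent_to_na(x)
  key <- tolower(gsub("[^a-z]", "", tolower(x)))
  map <- c(benign = "benign", likelybenign = "likely_benign",
           likeybenign = "likely_benign",
           vus = "vus", uncertainsignificance = "vus",
           variantofunknownsignificance = "vus",
           likelypathogenic = "likely_pathogenic",
           likeypathogenic = "likely_pathogenic",
           pathogenic = "pathogenic")
  out <- unname(map[key])
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop_format(sprintf("unrecognized ACMG verdict '%s'", x[which(bad)[1L]]))
  }
  out
}

# Split a combined "Verdict (CODE1,CODE2)" cell into its parts.
parse_acmg_field <- function(text, lenient = TRUE) {
  text <- absent_to_na(text)
  if (is.na(text)) return(list(verdict = NA_character_, codes = character(0)))
  m <- regmatches(text, regexec("^([^(]+?)\\s*(\\(([^)]*)\\))?$", text))[[1]]
  verdict <- normalize_verdict(m[2])
  codes <- if (length(m) >= 4 && nzchar(m[4])) {
    parse_evidence_codes(m[4], lenient = lenient)
  } else character(0)
  list(verdict = verdict, codes = codes)
}

#' Audit externally assigned ACMG verdicts against recomputed ones
#'
#' Re-derives the verdict for every annotated variant from its evidence
#' codes with [combine_acmg()] and compares it with the verdict carried in
#' the annotation (commercial interpretation platforms apply modified,
#' point-based rules, so divergences are expected audit findings rather
#' than errors). Records without evidence codes are skipped and counted.
#'
#' @param annotations Annotation tibble (needs `acmg_codes` and
#'   `acmg_verdict`; `gene`/`hgvs_p` used for labels when present).
#' @param lenient Passed to [parse_evidence_codes()].
#' @return A tibble with `key, gene, label, ingested, recomputed, agree`,
#'   with attributes `n_skipped` (records lacking codes) and `agreement`
#'   (fraction of audited records that agree).
#' @export
audit_verdicts <- function(annotations, lenient = TRUE) {
  if (nrow(annotations) == 0L) {
    out <- tibble(key = character(), gene = character(), label = character(),
                  ingested = character(), recomputed = character(),
                  agree = logical())
    attr(out, "n_skipped") <- 0L
    attr(out, "agreement") <- NA_real_
    return(out)
  }
  codes_raw <- annotations$acmg_codes
  has_codes <- !is.na(absent_to_na(codes_raw))
  aud <- annotations[has_codes, , drop = FALSE]
  recomputed <- vapply(aud$acmg_codes, function(s) {
    combine_acmg(parse_evidence_codes(s, lenient = lenient))
  }, character(1), USE.NAMES = FALSE)
  label <- paste0(aud$gene, ":",
                  ifelse(is.na(aud$hgvs_p), aud$hgvs_c, aud$hgvs_p))
  out <- tibble(key = aud$key %||% variant_key(aud$chrom, aud$pos, aud$ref,
                                               aud$alt),
                gene = aud$gene, label = label,
                ingested = aud$acmg_verdict, recomputed = recomputed,
                agree = !is.na(aud$acmg_verdict) &
                  aud$acmg_verdict == recomputed)
  attr(out, "n_skipped") <- sum(!has_codes)
  attr(out, "agreement") <- if (nrow(out)) mean(out$agree) else NA_real_
  out
}
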