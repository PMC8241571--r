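#' Default pipeline thresholds
#'
#' Every tunable threshold in the toolkit, grouped by stage, at its standard
#' value. Functions default to these; [read_config()] overrides them from a
#' sectioned `key = value` file.
#'
#' @return A named list of lists: `classify`, `quality`, `altcode`, `votu`,
#'   `aai`, `taxonomy`, `host`, `phylo`.
#' @export
default_config <- function() {
  list(
    classify = list(
      hmm_evalue_max = 1e-10,     # top-hit protein classification
      min_contig_length = 1000,   # unit of analysis
      benchmark_lengths_kb = c(1, 2, 5, 10, 20, 50, 100),
      fpr_weight = 50             # score = TPR - fpr_weight * FPR
    ),
    quality = list(
      min_terminal_repeat = 20,       # bp, DTR and ITR
      max_terminal_repeat = 5000,     # search upper bound
      large_repeat_seed = 100,        # bp exact seed for self-repeats
      large_repeat_max_span = 0.30,   # strict > rejects
      complete_min_completeness = 90, # strict >, with repeat/provirus evidence
      rrna_min_coverage = 0.70,
      rrna_max_evalue = 1e-5
    ),
    altcode = list(
      min_length = 10000,   # strict >
      max_gc = 0.50,        # strict <
      margin = 1.10,        # alt total must be >= margin * standard total
      min_orf_codons = 30   # naive ORF scorer
    ),
    votu = list(
      min_ani = 95, min_af = 85,       # species clustering
      min_alignment_pident = 90,       # local alignments entering ANI
      derep_revcomp = TRUE,
      aligner_max_length = 100000
    ),
    aai = list(
      max_evalue = 1e-5,
      family = list(min_aai = 20, min_shared = 10, inflation = 1.2),
      genus  = list(min_aai = 50, min_shared = 20, inflation = 2.0),
      mcl = list(prune = 1e-5, max_iter = 100, tol = 1e-6)
    ),
    taxonomy = list(
      next_hit_fraction = 0.75,  # "within 25% of the top hit"
      min_agreement = 0.70,      # strict >
      family_min_proteins = 2, family_min_identity = 30,
      genus_min_proteins = 3, genus_min_mean_identity = 40
    ),
    host = list(
      spacer_min_coverage = 0.95, spacer_max_edits = 1,
      genome_match_min_length = 1000, genome_match_min_identity = 96,
      decontaminate_min_host_fraction = 0.50,
      min_agreement = 0.70
    ),
    phylo = list(
      max_gap_fraction = 0.5,      # columns with >= this removed
      min_markers = 3,             # inclusive
      min_col_fraction = 0.05,     # strict >
      snp_min_site_coverage = 0.5, # inclusive
      snp_min_genome_data = 0.5    # inclusive
    )
  )
}

#' Read a sectioned key = value configuration file
#'
#' Lines are `key = value` grouped under `[section]` headers; `#` starts a
#' comment. Values are parsed as numeric where possible, `true`/`false` as
#' logical, and comma-separated values as vectors. Keys present in the file
#' override [default_config()]; unknown sections or keys are an error so
#' typos do not silently fall back to defaults.
#'
#' @param path Path to the configuration file.
#' @return The merged configuration list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- default_config()
  lines <- sub("#.*$", "", readLines(path))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (!section %in% names(cfg)) {
        abort(paste0("unknown config section: ", section))
      }
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) abort("config entries must appear under a [section]")
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!key %in% names(cfg[[section]])) {
        abort(paste0("unknown config key: ", section, ".", key))
      }
      cfg[[section]][[key]] <- parse_config_value(val)
    } else {
      abort(paste0("cannot parse config line: ", ln))
    }
  }
  cfg
}

parse_config_value <- function(val) {
  parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
  if (all(tolower(parts) %in% c("true", "false"))) {
    return(tolower(parts) == "true")
  }
  num <- suppressWarnings(as.numeric(parts))
  if (!anyNA(num)) return(num)
  parts
}
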