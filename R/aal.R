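#' AAL-90 cerebral parcellation labels
#'
#' Region abbreviations and names for the 90-region automated anatomical
#' labelling (AAL) cerebral parcellation (45 regions per hemisphere,
#' cerebellum excluded), in conventional atlas order with left/right pairs
#' interleaved. These are the node labels used when a cohort has 90 regions.
#'
#' @return A tibble with columns `index`, `abbreviation` (e.g. `"SFGdor.R"`),
#'   `name`, and `hemisphere` (`"L"`/`"R"`).
#' @export
#' @examples
#' aal90_regions()
aal90_regions <- function() {
  abb <- c(
    "PreCG", "SFGdor", "ORBsup", "MFG", "ORBmid", "IFGoperc", "IFGtriang",
    "ORBinf", "ROL", "SMA", "OLF", "SFGmed", "ORBsupmed", "REC", "INS",
    "ACG", "DCG", "PCG", "HIP", "PHG", "AMYG", "CAL", "CUN", "LING",
    "SOG", "MOG", "IOG", "FFG", "PoCG", "SPG", "IPL", "SMG", "ANG",
    "PCUN", "PCL", "CAU", "PUT", "PAL", "THA", "HES", "STG", "TPOsup",
    "MTG", "TPOmid", "ITG"
  )
  nm <- c(
    "Precentral gyrus", "Superior frontal gyrus, dorsolateral",
    "Superior frontal gyrus, orbital part", "Middle frontal gyrus",
    "Middle frontal gyrus, orbital part",
    "Inferior frontal gyrus, opercular part",
    "Inferior frontal gyrus, triangular part",
    "Inferior frontal gyrus, orbital part", "Rolandic operculum",
    "Supplementary motor area", "Olfactory cortex",
    "Superior frontal gyrus, medial",
    "Superior frontal gyrus, medial orbital part", "Gyrus rectus", "Insula",
    "Anterior cingulate and paracingulate gyri",
    "Median cingulate and paracingulate gyri",
    "Posterior cingulate gyrus", "Hippocampus", "Parahippocampal gyrus",
    "Amygdala", "Calcarine fissure and surrounding cortex", "Cuneus",
    "Lingual gyrus", "Superior occipital gyrus", "Middle occipital gyrus",
    "Inferior occipital gyrus", "Fusiform gyrus", "Postcentral gyrus",
    "Superior parietal gyrus",
    "Inferior parietal, but supramarginal and angular gyri",
    "Supramarginal gyrus", "Angular gyrus", "Precuneus",
    "Paracentral lobule", "Caudate nucleus",
    "Lenticular nucleus, putamen", "Lenticular nucleus, pallidum",
    "Thalamus", "Heschl gyrus", "Superior temporal gyrus",
    "Temporal pole: superior temporal gyrus", "Middle temporal gyrus",
    "Temporal pole: middle temporal gyrus", "Inferior temporal gyrus"
  )
  tibble::tibble(
    index = seq_len(90L),
    abbreviation = paste0(rep(abb, each = 2), c(".L", ".R")),
    name = paste0(rep(nm, each = 2), rep(c(" (left)", " (right)"), 45)),
    hemisphere = rep(c("L", "R"), 45)
  )
}

# Node labels for an n-region cohort: AAL abbreviations at n = 90,
# zero-padded generic labels otherwise.
mn_region_names <- function(n_regions) {
  if (n_regions == 90L) {
    aal90_regions()$abbreviation
  } else {
    sprintf("R%0*d", max(2L, nchar(n_regions)), seq_len(n_regions))
  }
}
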