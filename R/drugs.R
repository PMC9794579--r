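#' The seven ionic channels a drug block set addresses
#'
#' Order is fixed and used throughout the package: block vectors, conductance
#' scale factors and current traces are all keyed by these names.
#'
#' @export
TDP_CHANNELS <- c("INa", "INaL", "ICaL", "IKr", "IKs", "IK1", "Ito")

#' TdP risk classes, in the fixed label order used by the classifier
#' @export
TDP_RISKS <- c("high", "intermediate", "low")

#' CiPA reference drugs with risk labels, clinical Cmax and train/test split
#'
#' The 28 CiPA reference compounds: 12 training drugs (4 per risk class) and
#' 16 test drugs (4 high, 7 intermediate, 5 low). `cmax` is the maximal free
#' clinical plasma concentration in nM; simulations are run at 1-4x `cmax`.
#'
#' @return A tibble with columns `drug`, `risk` (factor high/intermediate/low),
#'   `cmax` (nM) and `split` ("train"/"test").
#' @examples
#' fixture_drugs()
#' dplyr::count(fixture_drugs(), split, risk)
#' @export
fixture_drugs <- function() {
  tab <- tibble::tribble(
    ~drug,            ~risk,          ~cmax,  ~split,
    "Bepridil",       "high",           33,    "train",
    "Dofetilide",     "high",            2,    "train",
    "Sotalol",        "high",         1439,    "train",
    "Quinidine",      "high",         3237,    "train",
    "Cisapride",      "intermediate",    2.6,  "train",
    "Chlorpromazine", "intermediate",   38,    "train",
    "Ondansetron",    "intermediate",  139,    "train",
    "Terfenadine",    "intermediate",    4,    "train",
    "Diltiazem",      "low",           122,    "train",
    "Mexiletine",     "low",          4129,    "train",
    "Ranolazine",     "low",          1948.2,  "train",
    "Verapamil",      "low",            81,    "train",
    "Azimilide",      "high",           70,    "test",
    "Disopyramide",   "high",          742,    "test",
    "Ibutilide",      "high",          100,    "test",
    "Vandetanib",     "high",          255.4,  "test",
    "Astemizole",     "intermediate",    0.26, "test",
    "Clarithromycin", "intermediate", 1206,    "test",
    "Clozapine",      "intermediate",   71,    "test",
    "Domperidone",    "intermediate",   19,    "test",
    "Droperidol",     "intermediate",    6.33, "test",
    "Pimozide",       "intermediate",    0.431,"test",
    "Risperidone",    "intermediate",    1.81, "test",
    "Loratadine",     "low",             0.45, "test",
    "Metoprolol",     "low",          1800,    "test",
    "Nifedipine",     "low",             7.7,  "test",
    "Nitrendipine",   "low",             3.02, "test",
    "Tamoxifen",      "low",            21,    "test"
  )
  tab$risk <- factor(tab$risk, levels = TDP_RISKS)
  tab
}

assert_risk <- function(risk) {
  bad <- setdiff(unique(as.character(risk)), TDP_RISKS)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "unknown risk label(s): ", paste(bad, collapse = ", "),
      " (expected one of ", paste(TDP_RISKS, collapse = ", "), ")"
    ))
  }
  invisible(risk)
}
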