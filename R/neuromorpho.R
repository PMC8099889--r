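# Helper for fetching deposited reconstructions from NeuroMorpho.Org.
# Network access is required; downloaded files are ordinary SWC and feed
# straight into analyze_swc_dir().

#' Download reconstructions from NeuroMorpho.Org
#'
#' Queries the NeuroMorpho.Org REST API for an archive (lab) name and
#' downloads the standardized (CNG) SWC files into `dest`. Requires network
#' access; intended for reproducing published morphometry from deposited
#' reconstructions with [analyze_swc_dir()].
#'
#' @param archive Archive (lab) name as registered at NeuroMorpho.Org.
#' @param dest Destination directory.
#' @param max_neurons Safety cap on the number of files fetched.
#' @param base_url API base URL.
#' @param quiet Passed to [utils::download.file()].
#' @return Character vector of downloaded file paths.
#' @export
fetch_neuromorpho <- function(archive, dest,
                              max_neurons = 100,
                              base_url = "https://neuromorpho.org",
                              quiet = TRUE) {
  dir.create(dest, showWarnings = FALSE, recursive = TRUE)
  q <- sprintf("%s/api/neuron/select?q=archive:%s&size=%d",
               base_url, utils::URLencode(archive), as.integer(max_neurons))
  resp <- tryCatch(jsonlite::fromJSON(q), error = function(e)
    stop2("NeuroMorpho API query failed (network required): ",
          conditionMessage(e)))
  neurons <- resp$`_embedded`$neuronResources
  if (is.null(neurons) || nrow(neurons) == 0)
    stop2("no neurons found for archive '", archive, "'")
  paths <- character(0)
  for (i in seq_len(nrow(neurons))) {
    nm <- neurons$neuron_name[i]
    arch <- tolower(neurons$archive[i])
    url <- sprintf("%s/dableFiles/%s/CNG%%20version/%s.CNG.swc",
                   base_url, utils::URLencode(arch), utils::URLencode(nm))
    out <- file.path(dest, paste0(nm, ".swc"))
    ok <- tryCatch({
      utils::download.file(url, out, quiet = quiet, mode = "wb")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (ok) paths <- c(paths, out)
  }
  if (length(paths) == 0)
    stop2("no SWC files could be downloaded for archive '", archive, "'")
  paths
}
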