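#' Load the curated liver / pancreatic cancer hub dataset
#'
#' The package ships, as plain TSV under `extdata/`, a curated snapshot of
#' a published comparative hub analysis of liver and pancreatic cancer
#' protein-interaction networks: the two top-20 hub lists, the degree
#' table of the 18 hubs the lists share (K liver / K pancreas), the
#' prose-stated directed action relations among those hubs, and the
#' per-map isolated-node lists transcribed from the original action-map
#' figures. One curation choice: the activation partner acting on PTEN is
#' not named in the source material, which states only that PTEN is
#' exclusively activated; TP53 — described there as the central connector
#' of every action map — is encoded as the acting partner.
#'
#' The isolated-node lists are kept as data of their own rather than being
#' re-derived from the shipped edges: the original figures contain more
#' edges than the prose enumerates, so edge-derived isolation would
#' overcount. Counts such as inhibition-map participation use these lists.
#'
#' @return a list with components:
#'   \describe{
#'     \item{liverHubs}{ordered character vector of 20 gene symbols.}
#'     \item{pancreasHubs}{ordered character vector of 20 gene symbols.}
#'     \item{hubDegrees}{data.frame `symbol`, `kLiver`, `kPancreas` over
#'       the 18 shared hubs, in curated order.}
#'     \item{actions}{action-record data.frame as from [readActions()].}
#'     \item{isolatedNodes}{named list of character vectors, one per map
#'       (`expression`, `activation`, `inhibition`).}
#'   }
#' @examples
#' fx <- loadCuratedHubData()
#' length(intersect(fx$liverHubs, fx$pancreasHubs))  # 18
#' @export
loadCuratedHubData <- function() {
  ext <- function(f) system.file("extdata", f, package = "HubScreen",
                                 mustWork = TRUE)
  liver <- read.delim(ext("liver_hubs.tsv"), stringsAsFactors = FALSE)
  panc <- read.delim(ext("pancreas_hubs.tsv"), stringsAsFactors = FALSE)
  deg <- read.delim(ext("hub_degrees.tsv"), stringsAsFactors = FALSE)
  iso <- read.delim(ext("isolated_nodes.tsv"), stringsAsFactors = FALSE)
  list(
    liverHubs = liver$symbol[order(liver$rank)],
    pancreasHubs = panc$symbol[order(panc$rank)],
    hubDegrees = data.frame(symbol = deg$symbol,
                            kLiver = as.integer(deg$k_liver),
                            kPancreas = as.integer(deg$k_pancreas),
                            stringsAsFactors = FALSE),
    actions = readActions(ext("hub_actions.tsv")),
    isolatedNodes = lapply(split(iso$symbol, iso$map), as.character)
  )
}
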