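## Four-class species rule set applied to delineated crowns.

.classLevels <- c("sapote", "overo", "algarrobo_alive", "algarrobo_dead")

#' Classify crowns by the threshold rule set
#'
#' Green-vegetation crowns are Sapote when mean GV is at or above
#' \code{sapoteGdviMin}, otherwise alive Algarrobo. Non-photosynthetic
#' crowns are dead Algarrobo when both large (pixel area at or above
#' \code{deadAreaMinPx}) and tall (object CHM above \code{chmBushMaxM}),
#' and Overo when both small and low. NPV crowns satisfying neither printed
#' conjunction (small-and-tall, large-and-low) are resolved by the CHM test
#' alone — height is what separates a tree from a bush — with a warning.
#' Classification is a pure function of the crown features and the
#' configuration.
#'
#' @param features Data frame of crown features (rows of a
#'   \linkS4class{CrownSet} table): needs \code{mean_gv}, \code{mean_npv},
#'   \code{area_px}, \code{max_chm}/\code{mean_chm} and, if present,
#'   \code{vegetation_kind}.
#' @param cfg A \linkS4class{RuleConfig}.
#' @return Character vector of class labels.
#' @export
classifyCrown <- function(features, cfg = ruleConfig()) {
  if (!nrow(features)) return(character(0))
  need <- c("mean_gv", "mean_npv", "area_px",
            paste0(cfg@chmStatistic, "_chm"))
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("missing crown features: ", paste(miss, collapse = ", "))
  chmStat <- features[[paste0(cfg@chmStatistic, "_chm")]]
  isNpv <- if ("vegetation_kind" %in% names(features))
    features$vegetation_kind == "npv"
  else features$mean_npv > cfg@npvThreshold
  out <- ifelse(features$mean_gv >= cfg@sapoteGdviMin, "sapote",
                "algarrobo_alive")
  big <- features$area_px >= cfg@deadAreaMinPx
  tall <- chmStat > cfg@chmBushMaxM
  npvLab <- ifelse(big & tall, "algarrobo_dead",
                   ifelse(!big & !tall, "overo",
                          ifelse(tall, "algarrobo_dead", "overo")))
  odd <- isNpv & (big != tall)
  if (any(odd))
    warning(sum(odd), " NPV crown(s) outside the printed rule quadrants; ",
            "resolved by the CHM test alone")
  out[isNpv] <- npvLab[isNpv]
  out
}

#' Classify every crown and tally the map
#'
#' Applies \code{\link{classifyCrown}} to each crown and summarises the
#' result. Overo, a bush, is mapped but not counted as a tree: the tree
#' count covers Sapote and alive/dead Algarrobo only.
#'
#' @param crownSet A \linkS4class{CrownSet} from
#'   \code{\link{delineateCrowns}}.
#' @param cfg A \linkS4class{RuleConfig}.
#' @return A \linkS4class{ClassifiedMap}.
#' @export
classifyAll <- function(crownSet, cfg = ruleConfig()) {
  tb <- crownSet@table
  lab <- if (nrow(tb)) classifyCrown(tb, cfg) else character(0)
  if (nrow(tb)) crownSet@table$class <- lab
  counts <- setNames(integer(length(.classLevels)), .classLevels)
  areas <- setNames(numeric(length(.classLevels)), .classLevels)
  for (k in .classLevels) {
    counts[k] <- sum(lab == k)
    areas[k] <- sum(tb$area_m2[lab == k])
  }
  new("ClassifiedMap", crowns = crownSet, counts = counts,
      areaTotals = areas,
      treeCount = as.integer(sum(counts[setdiff(.classLevels, "overo")])))
}
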