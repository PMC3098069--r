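# Small hand-built partonomies used across test files.

# a human-like body with organ systems and cardinal body parts: organs sit
# inside body parts AND inside the respiratory system, but body parts are
# not parts of organ systems (the classic adjacency failure of
# single-perspective schemes)
respiratory_partonomy <- function() {
  types <- list(
    material_type("Organ", "object"),
    material_type("Organism", "object"),
    material_type("Organ system", "fiat_object_part",
                  name_giving = "Organism"),
    material_type("Cardinal body part", "fiat_object_part",
                  name_giving = "Organism"))
  instances <- data.frame(
    id = c("body", "resp_system", "head", "chest", "lung", "nose"),
    type_id = c("Organism", "Organ system", "Cardinal body part",
                "Cardinal body part", "Organ", "Organ"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    child = c("lung", "nose", "lung", "nose", "head", "chest",
              "resp_system"),
    relation = "proper_part_of",
    parent = c("chest", "head", "resp_system", "resp_system", "body",
               "body", "body"),
    stringsAsFactors = FALSE)
  partonomy(types, instances, edges)
}

# a would-be cell aggregate whose instances also contain extracellular
# matrix molecules
misused_aggregate_partonomy <- function() {
  types <- list(
    material_type("cell", "object"),
    material_type("ecm_mol", "object", label = "ECM"),
    material_type("organ", "object"),
    material_type("cell_agg", "object_aggregate", label = "cell aggregate",
                  name_giving = "cell"))
  instances <- data.frame(
    id = c("organ1", "agg1", "c1", "c2", "e1"),
    type_id = c("organ", "cell_agg", "cell", "cell", "ecm_mol"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    child = c("c1", "c2", "e1", "agg1"),
    relation = "direct_proper_part_of",
    parent = c("agg1", "agg1", "agg1", "organ1"),
    stringsAsFactors = FALSE)
  partonomy(types, instances, edges)
}

# fig11 extended with a deeper fiat part at the fine end of the chain
fig11_regranulated <- function() {
  p <- fixture("fig11_organ")
  types <- rbind(p$types, granpart:::type_table(list(material_type(
    "fop0", "fiat_object_part", label = "fiat organ part 0",
    name_giving = "organ"))))
  instances <- rbind(p$instances,
                     data.frame(id = "f0", type_id = "fop0",
                                stringsAsFactors = FALSE))
  edges <- p$edges
  edges$parent[edges$child == "cell1"] <- "f0"
  edges <- rbind(edges, data.frame(child = "f0",
                                   relation = "direct_proper_part_of",
                                   parent = "f1", stringsAsFactors = FALSE))
  partonomy(types, instances, edges)
}

instance_values <- function(v) {
  out <- v$instances[c("instance", "rep_num", "rep_den")]
  out <- out[order(out$instance), ]
  rownames(out) <- NULL
  out
}
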