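# Static element-definition table for the supported R4 subset.
#
# Transcribed once from the published R4 structure definitions; shipped as
# code so builds are hermetic (no runtime download). Row order is FHIR
# definition order and drives canonical key ordering. `max = *` means
# unbounded; a name ending in [x] is a choice element whose `types` lists the
# allowed datatypes; a type of `=Path` recurses into the backbone defined at
# Path (for self-nesting items).

fhir_defs_raw <- c(
  # --- datatypes -----------------------------------------------------------
  "Meta.versionId 0 1 id",
  "Meta.lastUpdated 0 1 instant",
  "Meta.source 0 1 uri",
  "Meta.profile 0 * canonical",
  "Meta.security 0 * Coding",
  "Meta.tag 0 * Coding",
  "Narrative.status 1 1 code",
  "Narrative.div 1 1 xhtml",
  "Extension.url 1 1 uri",
  paste0("Extension.value[x] 0 1 boolean,integer,decimal,string,date,dateTime,",
         "instant,time,code,uri,url,canonical,markdown,base64Binary,uuid,",
         "Coding,CodeableConcept,Quantity,Reference,Period,Identifier,Attachment"),
  "Coding.system 0 1 uri",
  "Coding.version 0 1 string",
  "Coding.code 0 1 code",
  "Coding.display 0 1 string",
  "Coding.userSelected 0 1 boolean",
  "CodeableConcept.coding 0 * Coding",
  "CodeableConcept.text 0 1 string",
  "Quantity.value 0 1 decimal",
  "Quantity.comparator 0 1 code",
  "Quantity.unit 0 1 string",
  "Quantity.system 0 1 uri",
  "Quantity.code 0 1 code",
  "Duration.value 0 1 decimal",
  "Duration.comparator 0 1 code",
  "Duration.unit 0 1 string",
  "Duration.system 0 1 uri",
  "Duration.code 0 1 code",
  "Range.low 0 1 Quantity",
  "Range.high 0 1 Quantity",
  "Ratio.numerator 0 1 Quantity",
  "Ratio.denominator 0 1 Quantity",
  "Period.start 0 1 dateTime",
  "Period.end 0 1 dateTime",
  "Reference.reference 0 1 string",
  "Reference.type 0 1 uri",
  "Reference.identifier 0 1 Identifier",
  "Reference.display 0 1 string",
  "Identifier.use 0 1 code",
  "Identifier.type 0 1 CodeableConcept",
  "Identifier.system 0 1 uri",
  "Identifier.value 0 1 string",
  "Identifier.period 0 1 Period",
  "Attachment.contentType 0 1 code",
  "Attachment.language 0 1 code",
  "Attachment.data 0 1 base64Binary",
  "Attachment.url 0 1 url",
  "Attachment.size 0 1 unsignedInt",
  "Attachment.hash 0 1 base64Binary",
  "Attachment.title 0 1 string",
  "Attachment.creation 0 1 dateTime",
  "Annotation.author[x] 0 1 Reference,string",
  "Annotation.time 0 1 dateTime",
  "Annotation.text 1 1 markdown",
  "HumanName.use 0 1 code",
  "HumanName.text 0 1 string",
  "HumanName.family 0 1 string",
  "HumanName.given 0 * string",
  "HumanName.prefix 0 * string",
  "HumanName.suffix 0 * string",
  "HumanName.period 0 1 Period",
  "ContactPoint.system 0 1 code",
  "ContactPoint.value 0 1 string",
  "ContactPoint.use 0 1 code",
  "ContactPoint.rank 0 1 positiveInt",
  "ContactPoint.period 0 1 Period",
  "Timing.event 0 * dateTime",
  "Timing.repeat 0 1 Element",
  "Timing.repeat.bounds[x] 0 1 Duration,Range,Period",
  "Timing.repeat.count 0 1 positiveInt",
  "Timing.repeat.countMax 0 1 positiveInt",
  "Timing.repeat.duration 0 1 decimal",
  "Timing.repeat.durationMax 0 1 decimal",
  "Timing.repeat.durationUnit 0 1 code",
  "Timing.repeat.frequency 0 1 positiveInt",
  "Timing.repeat.frequencyMax 0 1 positiveInt",
  "Timing.repeat.period 0 1 decimal",
  "Timing.repeat.periodMax 0 1 decimal",
  "Timing.repeat.periodUnit 0 1 code",
  "Timing.repeat.dayOfWeek 0 * code",
  "Timing.repeat.timeOfDay 0 * time",
  "Timing.repeat.when 0 * code",
  "Timing.repeat.offset 0 1 unsignedInt",
  "Timing.code 0 1 CodeableConcept",
  # --- Patient / Practitioner ---------------------------------------------
  "Patient.identifier 0 * Identifier",
  "Patient.active 0 1 boolean",
  "Patient.name 0 * HumanName",
  "Patient.telecom 0 * ContactPoint",
  "Patient.gender 0 1 code",
  "Patient.birthDate 0 1 date",
  "Practitioner.identifier 0 * Identifier",
  "Practitioner.active 0 1 boolean",
  "Practitioner.name 0 * HumanName",
  "Practitioner.telecom 0 * ContactPoint",
  "Practitioner.gender 0 1 code",
  "Practitioner.birthDate 0 1 date",
  # --- Questionnaire -------------------------------------------------------
  "Questionnaire.url 0 1 uri",
  "Questionnaire.identifier 0 * Identifier",
  "Questionnaire.version 0 1 string",
  "Questionnaire.name 0 1 string",
  "Questionnaire.title 0 1 string",
  "Questionnaire.status 1 1 code",
  "Questionnaire.experimental 0 1 boolean",
  "Questionnaire.subjectType 0 * code",
  "Questionnaire.date 0 1 dateTime",
  "Questionnaire.publisher 0 1 string",
  "Questionnaire.description 0 1 markdown",
  "Questionnaire.code 0 * Coding",
  "Questionnaire.item 0 * BackboneElement",
  "Questionnaire.item.linkId 1 1 string",
  "Questionnaire.item.definition 0 1 uri",
  "Questionnaire.item.code 0 * Coding",
  "Questionnaire.item.prefix 0 1 string",
  "Questionnaire.item.text 0 1 string",
  "Questionnaire.item.type 1 1 code",
  "Questionnaire.item.enableWhen 0 * BackboneElement",
  "Questionnaire.item.enableWhen.question 1 1 string",
  "Questionnaire.item.enableWhen.operator 1 1 code",
  paste0("Questionnaire.item.enableWhen.answer[x] 1 1 boolean,decimal,integer,",
         "date,dateTime,time,string,Coding,Quantity,Reference"),
  "Questionnaire.item.enableBehavior 0 1 code",
  "Questionnaire.item.required 0 1 boolean",
  "Questionnaire.item.repeats 0 1 boolean",
  "Questionnaire.item.readOnly 0 1 boolean",
  "Questionnaire.item.maxLength 0 1 integer",
  "Questionnaire.item.answerValueSet 0 1 canonical",
  "Questionnaire.item.answerOption 0 * BackboneElement",
  "Questionnaire.item.answerOption.value[x] 1 1 integer,date,time,string,Coding,Reference",
  "Questionnaire.item.answerOption.initialSelected 0 1 boolean",
  "Questionnaire.item.initial 0 * BackboneElement",
  paste0("Questionnaire.item.initial.value[x] 1 1 boolean,decimal,integer,date,",
         "dateTime,time,string,uri,Attachment,Coding,Quantity,Reference"),
  "Questionnaire.item.item 0 * =Questionnaire.item",
  # --- QuestionnaireResponse ----------------------------------------------
  "QuestionnaireResponse.identifier 0 1 Identifier",
  "QuestionnaireResponse.basedOn 0 * Reference",
  "QuestionnaireResponse.partOf 0 * Reference",
  "QuestionnaireResponse.questionnaire 0 1 canonical",
  "QuestionnaireResponse.status 1 1 code",
  "QuestionnaireResponse.subject 0 1 Reference",
  "QuestionnaireResponse.encounter 0 1 Reference",
  "QuestionnaireResponse.authored 0 1 dateTime",
  "QuestionnaireResponse.author 0 1 Reference",
  "QuestionnaireResponse.source 0 1 Reference",
  "QuestionnaireResponse.item 0 * BackboneElement",
  "QuestionnaireResponse.item.linkId 1 1 string",
  "QuestionnaireResponse.item.definition 0 1 uri",
  "QuestionnaireResponse.item.text 0 1 string",
  "QuestionnaireResponse.item.answer 0 * BackboneElement",
  paste0("QuestionnaireResponse.item.answer.value[x] 0 1 boolean,decimal,",
         "integer,date,dateTime,time,string,uri,Attachment,Coding,Quantity,Reference"),
  "QuestionnaireResponse.item.answer.item 0 * =QuestionnaireResponse.item",
  "QuestionnaireResponse.item.item 0 * =QuestionnaireResponse.item",
  # --- ServiceRequest ------------------------------------------------------
  "ServiceRequest.identifier 0 * Identifier",
  "ServiceRequest.instantiatesCanonical 0 * canonical",
  "ServiceRequest.instantiatesUri 0 * uri",
  "ServiceRequest.basedOn 0 * Reference",
  "ServiceRequest.replaces 0 * Reference",
  "ServiceRequest.requisition 0 1 Identifier",
  "ServiceRequest.status 1 1 code",
  "ServiceRequest.intent 1 1 code",
  "ServiceRequest.category 0 * CodeableConcept",
  "ServiceRequest.priority 0 1 code",
  "ServiceRequest.doNotPerform 0 1 boolean",
  "ServiceRequest.code 0 1 CodeableConcept",
  "ServiceRequest.orderDetail 0 * CodeableConcept",
  "ServiceRequest.quantity[x] 0 1 Quantity,Ratio,Range",
  "ServiceRequest.subject 1 1 Reference",
  "ServiceRequest.encounter 0 1 Reference",
  "ServiceRequest.occurrence[x] 0 1 dateTime,Period,Timing",
  "ServiceRequest.asNeeded[x] 0 1 boolean,CodeableConcept",
  "ServiceRequest.authoredOn 0 1 dateTime",
  "ServiceRequest.requester 0 1 Reference",
  "ServiceRequest.performerType 0 1 CodeableConcept",
  "ServiceRequest.performer 0 * Reference",
  "ServiceRequest.locationCode 0 * CodeableConcept",
  "ServiceRequest.reasonCode 0 * CodeableConcept",
  "ServiceRequest.reasonReference 0 * Reference",
  "ServiceRequest.supportingInfo 0 * Reference",
  "ServiceRequest.note 0 * Annotation",
  "ServiceRequest.patientInstruction 0 1 string",
  # --- Observation ---------------------------------------------------------
  "Observation.identifier 0 * Identifier",
  "Observation.basedOn 0 * Reference",
  "Observation.partOf 0 * Reference",
  "Observation.status 1 1 code",
  "Observation.category 0 * CodeableConcept",
  "Observation.code 1 1 CodeableConcept",
  "Observation.subject 0 1 Reference",
  "Observation.focus 0 * Reference",
  "Observation.encounter 0 1 Reference",
  "Observation.effective[x] 0 1 dateTime,Period,Timing,instant",
  "Observation.issued 0 1 instant",
  "Observation.performer 0 * Reference",
  paste0("Observation.value[x] 0 1 Quantity,CodeableConcept,string,boolean,",
         "integer,Range,Ratio,time,dateTime,Period"),
  "Observation.dataAbsentReason 0 1 CodeableConcept",
  "Observation.interpretation 0 * CodeableConcept",
  "Observation.note 0 * Annotation",
  "Observation.bodySite 0 1 CodeableConcept",
  "Observation.method 0 1 CodeableConcept",
  "Observation.specimen 0 1 Reference",
  "Observation.device 0 1 Reference",
  "Observation.referenceRange 0 * BackboneElement",
  "Observation.referenceRange.low 0 1 Quantity",
  "Observation.referenceRange.high 0 1 Quantity",
  "Observation.referenceRange.text 0 1 string",
  "Observation.hasMember 0 * Reference",
  "Observation.derivedFrom 0 * Reference",
  "Observation.component 0 * BackboneElement",
  "Observation.component.code 1 1 CodeableConcept",
  paste0("Observation.component.value[x] 0 1 Quantity,CodeableConcept,string,",
         "boolean,integer,Range,Ratio,time,dateTime,Period"),
  "Observation.component.dataAbsentReason 0 1 CodeableConcept",
  "Observation.component.interpretation 0 * CodeableConcept",
  # --- DocumentReference ---------------------------------------------------
  "DocumentReference.masterIdentifier 0 1 Identifier",
  "DocumentReference.identifier 0 * Identifier",
  "DocumentReference.status 1 1 code",
  "DocumentReference.docStatus 0 1 code",
  "DocumentReference.type 0 1 CodeableConcept",
  "DocumentReference.category 0 * CodeableConcept",
  "DocumentReference.subject 0 1 Reference",
  "DocumentReference.date 0 1 instant",
  "DocumentReference.author 0 * Reference",
  "DocumentReference.authenticator 0 1 Reference",
  "DocumentReference.custodian 0 1 Reference",
  "DocumentReference.description 0 1 string",
  "DocumentReference.securityLabel 0 * CodeableConcept",
  "DocumentReference.content 1 * BackboneElement",
  "DocumentReference.content.attachment 1 1 Attachment",
  "DocumentReference.content.format 0 1 Coding",
  "DocumentReference.context 0 1 BackboneElement",
  "DocumentReference.context.encounter 0 * Reference",
  "DocumentReference.context.event 0 * CodeableConcept",
  "DocumentReference.context.period 0 1 Period",
  "DocumentReference.context.related 0 * Reference",
  # --- Media ---------------------------------------------------------------
  "Media.identifier 0 * Identifier",
  "Media.basedOn 0 * Reference",
  "Media.partOf 0 * Reference",
  "Media.status 1 1 code",
  "Media.type 0 1 CodeableConcept",
  "Media.modality 0 1 CodeableConcept",
  "Media.view 0 1 CodeableConcept",
  "Media.subject 0 1 Reference",
  "Media.encounter 0 1 Reference",
  "Media.created[x] 0 1 dateTime,Period",
  "Media.issued 0 1 instant",
  "Media.operator 0 1 Reference",
  "Media.reasonCode 0 * CodeableConcept",
  "Media.bodySite 0 1 CodeableConcept",
  "Media.deviceName 0 1 string",
  "Media.device 0 1 Reference",
  "Media.height 0 1 positiveInt",
  "Media.width 0 1 positiveInt",
  "Media.frames 0 1 positiveInt",
  "Media.duration 0 1 decimal",
  "Media.content 1 1 Attachment",
  "Media.note 0 * Annotation",
  # --- ValueSet ------------------------------------------------------------
  "ValueSet.url 0 1 uri",
  "ValueSet.identifier 0 * Identifier",
  "ValueSet.version 0 1 string",
  "ValueSet.name 0 1 string",
  "ValueSet.title 0 1 string",
  "ValueSet.status 1 1 code",
  "ValueSet.experimental 0 1 boolean",
  "ValueSet.date 0 1 dateTime",
  "ValueSet.publisher 0 1 string",
  "ValueSet.description 0 1 markdown",
  "ValueSet.compose 0 1 BackboneElement",
  "ValueSet.compose.lockedDate 0 1 date",
  "ValueSet.compose.inactive 0 1 boolean",
  "ValueSet.compose.include 1 * BackboneElement",
  "ValueSet.compose.include.system 0 1 uri",
  "ValueSet.compose.include.version 0 1 string",
  "ValueSet.compose.include.concept 0 * BackboneElement",
  "ValueSet.compose.include.concept.code 1 1 code",
  "ValueSet.compose.include.concept.display 0 1 string",
  "ValueSet.compose.include.valueSet 0 * canonical",
  "ValueSet.compose.exclude 0 * =ValueSet.compose.include",
  # --- Bundle --------------------------------------------------------------
  "Bundle.identifier 0 1 Identifier",
  "Bundle.type 1 1 code",
  "Bundle.timestamp 0 1 instant",
  "Bundle.total 0 1 unsignedInt",
  "Bundle.link 0 * BackboneElement",
  "Bundle.link.relation 1 1 string",
  "Bundle.link.url 1 1 uri",
  "Bundle.entry 0 * BackboneElement",
  "Bundle.entry.link 0 * =Bundle.link",
  "Bundle.entry.fullUrl 0 1 uri",
  "Bundle.entry.resource 0 1 Resource",
  "Bundle.entry.search 0 1 BackboneElement",
  "Bundle.entry.search.mode 0 1 code",
  "Bundle.entry.search.score 0 1 decimal",
  "Bundle.entry.request 0 1 BackboneElement",
  "Bundle.entry.request.method 1 1 code",
  "Bundle.entry.request.url 1 1 uri",
  "Bundle.entry.request.ifNoneMatch 0 1 string",
  "Bundle.entry.request.ifModifiedSince 0 1 instant",
  "Bundle.entry.request.ifMatch 0 1 string",
  "Bundle.entry.request.ifNoneExist 0 1 string",
  "Bundle.entry.response 0 1 BackboneElement",
  "Bundle.entry.response.status 1 1 string",
  "Bundle.entry.response.location 0 1 uri",
  "Bundle.entry.response.etag 0 1 string",
  "Bundle.entry.response.lastModified 0 1 instant",
  "Bundle.entry.response.outcome 0 1 Resource",
  # --- OperationOutcome ----------------------------------------------------
  "OperationOutcome.issue 1 * BackboneElement",
  "OperationOutcome.issue.severity 1 1 code",
  "OperationOutcome.issue.code 1 1 code",
  "OperationOutcome.issue.details 0 1 CodeableConcept",
  "OperationOutcome.issue.diagnostics 0 1 string",
  "OperationOutcome.issue.location 0 * string",
  "OperationOutcome.issue.expression 0 * string"
)

.defs_cache <- new.env(parent = emptyenv())

#' Element definitions for the supported R4 resource subset
#'
#' A static table transcribed from the published R4 structure definitions:
#' one row per element, with dotted `path`, cardinality bounds, allowed
#' datatypes, and whether the element is a choice (`value[x]`-style). Row
#' order is FHIR definition order.
#'
#' @return A tibble with columns `path`, `parent`, `name`, `min`, `max`
#'   (`Inf` when unbounded), `types` (comma-separated tokens), `choice`.
#' @export
fhir_element_definitions <- function() {
  if (!is.null(.defs_cache$defs)) return(.defs_cache$defs)
  parts <- strsplit(fhir_defs_raw, " ", fixed = TRUE)
  path <- vapply(parts, `[[`, "", 1)
  defs <- tibble::tibble(
    path = path,
    parent = sub("\\.[^.]+$", "", path),
    name = sub("^.*\\.", "", path),
    min = as.numeric(vapply(parts, `[[`, "", 2)),
    max = as.numeric(sub("^\\*$", "Inf", vapply(parts, `[[`, "", 3))),
    types = vapply(parts, `[[`, "", 4),
    choice = grepl("\\[x\\]$", path)
  )
  .defs_cache$defs <- defs
  defs
}

# Children of a definition prefix (resource, datatype, or backbone path)
fhir_children <- function(prefix) {
  defs <- fhir_element_definitions()
  defs[defs$parent == prefix, , drop = FALSE]
}

fhir_complex_types <- function() {
  c("Meta", "Narrative", "Extension", "Coding", "CodeableConcept", "Quantity",
    "Duration", "Range", "Ratio", "Period", "Reference", "Identifier",
    "Attachment", "Annotation", "HumanName", "ContactPoint", "Timing")
}

fhir_primitive_types <- function() {
  c("boolean", "integer", "positiveInt", "unsignedInt", "decimal", "string",
    "code", "id", "uri", "url", "canonical", "markdown", "base64Binary",
    "date", "dateTime", "instant", "time", "uuid", "xhtml")
}
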