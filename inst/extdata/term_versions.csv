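term_iri,term_localName,label,definition,issued,status,abcd_equivalence,notes
"http://rs.tdwg.org/chrono/terms/ChronometricAge","chronometricAge","Chronometric Age","An approximation of a temporal position (in the sense conveyed by https://www.w3.org/TR/owl-time/#time:TemporalPosition) that is supported via evidence.","2021-02-21","recommended","",""
"http://rs.tdwg.org/chrono/terms/chronometricAgeID","chronometricAgeID","Chronometric Age ID","An identifier for the set of information associated with a ChronometricAge.","2021-02-21","recommended","",""
"http://rs.tdwg.org/chrono/terms/chronometricAgeReferences","chronometricAgeReferences","Chronometric Age References","A list (concatenated and separated) of identifiers (publication, bibliographic reference, global unique identifier, URI) of literature associated with the ChronometricAge.","2021-02-21","recommended","",""
"http://rs.tdwg.org/chrono/terms/chronometricAgeRemarks","chronometricAgeRemarks","Chronometric Age Remarks","Notes or comments about the ChronometricAge.","2021-02-21","recommended","",""
"http://rs.tdwg.org/chrono/terms/materialDated","materialDated","Material Dated","A description of the material on which the chronometricAgeProtocol was actually performed, if known.","2021-02-21","recommended","",""
"http://rs.tdwg.org/chrono/terms/materialDatedID","materialDatedID","Material Dated ID","An identifier for the MaterialSample on which the chronometricAgeProtocol was performed, if applicable.","2021-02-21","recommended","",""
"http://rs.tdwg.org/chrono/terms/materialDatedRelationship","materialDatedRelationship","Material Dated Relationship","The relationship of the materialDated to the subject of the ChronometricAge record, from which the ChronometricAge of the subject is inferred.","2021-02-21","recommended","",""
"http://rs.tdwg.org/chrono/terms/chronometricAgeProtocol","chronometricAgeProtocol","Chronometric Age Protocol","A description of or reference to the methods used to determine the chronometric age.","2021-02-21","recommended","",""
"http://rs.tdwg.org/chrono/terms/uncalibratedChronometricAge","uncalibratedChronometricAge","Uncalibrated Chronometric Age","The output of a dating assay before it is calibrated into an age using a specific conversion protocol.","2021-02-21","recommended","",""
"http://rs.tdwg.org/chrono/terms/verbatimChronometricAge","verbatimChronometricAge","Verbatim Chronometric Age","The verbatim age for a specimen, whether reported by a dating assay, associated references, or legacy information.","2021-02-21","recommended","",""
"http://rs.tdwg.org/chrono/terms/earliestChronometricAge","earliestChronometricAge","Earliest Chronometric Age","The maximum/earliest/oldest possible age of a specimen as determined by a dating method.","2021-02-21","recommended","",""
"http://rs.tdwg.org/chrono/terms/earliestChronometricAgeReferenceSystem","earliestChronometricAgeReferenceSystem","Earliest Chronometric Age Reference System","The reference system associated with the earliestChronometricAge.","2021-02-21","recommended","",""
"http://rs.tdwg.org/chrono/terms/latestChronometricAge","latestChronometricAge","Latest Chronometric Age","The minimum/latest/youngest possible age of a specimen as determined by a dating method.","2021-02-21","recommended","",""
"http://rs.tdwg.org/chrono/terms/latestChronometricAgeReferenceSystem","latestChronometricAgeReferenceSystem","Latest Chronometric Age Reference System","The reference system associated with the latestChronometricAge.","2021-02-21","recommended","",""
"http://rs.tdwg.org/chrono/terms/chronometricAgeConversionProtocol","chronometricAgeConversionProtocol","Chronometric Age Conversion Protocol","The method used for converting the uncalibratedChronometricAge into a chronometric age in years, as captured in the earliestChronometricAge, earliestChronometricAgeReferenceSystem, latestChronometricAge, and latestChronometricAgeReferenceSystem fields.","2021-02-21","recommended","",""
"http://rs.tdwg.org/chrono/terms/chronometricAgeUncertaintyInYears","chronometricAgeUncertaintyInYears","Chronometric Age Uncertainty In Years","The temporal uncertainty of the earliestChronometricAge and latestChronometicAge in years.","2021-02-21","recommended","",""
"http://rs.tdwg.org/chrono/terms/chronometricAgeUncertaintyMethod","chronometricAgeUncertaintyMethod","Chronometric Age Uncertainty Method","The method used to generate the value of chronometricAgeUncertaintyInYears.","2021-02-21","recommended","",""
"http://rs.tdwg.org/chrono/terms/chronometricAgeDeterminedBy","chronometricAgeDeterminedBy","Chronometric Age Determined By","A list (concatenated and separated) of names of people, groups, or organizations who determined the ChronometricAge.","2021-02-21","recommended","",""
"http://rs.tdwg.org/chrono/terms/chronometricAgeDeterminedDate","chronometricAgeDeterminedDate","Chronometric Age Determined Date","The date on which the ChronometricAge was determined.","2021-02-21","recommended","",""
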