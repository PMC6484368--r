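network,construct_kind,term,domain,definition
CESR,data_element,birth date,Birth,DEs related to birth-related variables
CESR,data_element,bdate,Birth,DEs related to birth-related variables
CESR,data_element,bone measured,Bone Measurement,DEs related to bone measurement variables
CESR,data_element,machine type used,Bone Measurement,DEs related to bone measurement variables
CESR,data_element,scan date,Bone Measurement,DEs related to bone measurement variables
CESR,data_element,facility name,Care Site,DEs related to place of care specific variables
CESR,data_element,principal diagnosis,Condition,DEs related primarily to condition-specific variables
CESR,data_element,diagnosis code type,Condition,DEs related primarily to condition-specific variables
CESR,data_element,original diagnosis,Condition,DEs related primarily to condition-specific variables
CESR,data_element,date,Date,DEs related to unspecified date variables
CESR,data_element,death date,Death,DEs related to death-specific variables
CESR,data_element,age at death,Death,DEs related to death-specific variables
CESR,data_element,enrollment start date,Enrollment,DEs related to enrollment-specific variables
CESR,data_element,enrollment end date,Enrollment,DEs related to enrollment-specific variables
CESR,data_element,enrollment basis,Enrollment,DEs related to enrollment-specific variables
CESR,data_element,Hispanic,Ethnicity,DEs related to ethnicity-specific variables
CESR,data_element,gender,Gender,DEs related to gender-specific variables
CESR,data_element,protocol ID,Internal ID,DEs defined by internally utilized constructions
CESR,data_element,row ID,Internal ID,DEs defined by internally utilized constructions
CESR,data_element,template ID,Internal ID,DEs defined by internally utilized constructions
CESR,data_element,test type,Lab,DEs related to lab-specific variables
CESR,data_element,specimen source,Lab,DEs related to lab-specific variables
CESR,data_element,modification measures,Lab,DEs related to lab-specific variables
CESR,data_element,primary language,Language,DEs related to speaking language variables
CESR,data_element,need for interpreter,Language,DEs related to speaking language variables
CESR,data_element,language usage,Language,DEs related to speaking language variables
CESR,data_element,refills,Medication,DEs related to medication-specific variables
CESR,data_element,quantity,Medication,DEs related to medication-specific variables
CESR,data_element,dosage form,Medication,DEs related to medication-specific variables
CESR,data_element,dosage amount,Medication,DEs related to medication-specific variables
CESR,data_element,order date,Medication,DEs related to medication-specific variables
CESR,data_element,prescription date,Medication,DEs related to medication-specific variables
CESR,data_element,infusion duration,Medication,DEs related to medication-specific variables
CESR,data_element,MRN,MRN,DEs related to medical record numbers
CESR,data_element,enrollment MRN,MRN,DEs related to medical record numbers
CESR,data_element,unit of measure,Observations,DEs related to ambiguous variables
CESR,data_element,type of activity,Observations,DEs related to ambiguous variables
CESR,data_element,message type,Observations,DEs related to ambiguous variables
CESR,data_element,CPT modifiers,Procedure,DEs related to procedure-specific variables
CESR,data_element,procedure date,Procedure,DEs related to procedure-specific variables
CESR,data_element,original procedure,Procedure,DEs related to procedure-specific variables
CESR,data_element,specialty,Provider,DEs related to provider-specific variables
CESR,data_element,provider demographics,Provider,DEs related to provider-specific variables
CESR,data_element,provider type,Provider,DEs related to provider-specific variables
CESR,data_element,race1,Race,DEs related to race-specific variables
CESR,data_element,race2,Race,DEs related to race-specific variables
CESR,data_element,non-Hispanic white,Race,DEs related to race-specific variables
CESR,data_element,smoking use,Social History,DEs related to social history variables
CESR,data_element,alcohol use,Social History,DEs related to social history variables
CESR,data_element,drug use,Social History,DEs related to social history variables
CESR,data_element,household income,Socioeconomic Factors,DEs related to socioeconomic variables
CESR,data_element,poverty status,Socioeconomic Factors,DEs related to socioeconomic variables
CESR,data_element,education level,Socioeconomic Factors,DEs related to socioeconomic variables
CESR,data_element,SSF measures,Tumor,DEs related to cancer-specific variables
CESR,data_element,stage of progression,Tumor,DEs related to cancer-specific variables
CESR,data_element,chemotherapy date,Tumor,DEs related to cancer-specific variables
CESR,data_element,inpatient length of stay,Visit,DEs related to visit-specific variables
CESR,data_element,discharge status,Visit,DEs related to visit-specific variables
CESR,data_element,admission type,Visit,DEs related to visit-specific variables
CESR,data_element,encounter dates,Visit,DEs related to visit-specific variables
CESR,data_element,weight measurements,Vital,DEs related to vital-specific variables
CESR,data_element,blood pressure measurements,Vital,DEs related to vital-specific variables
CESR,data_element,pulse measurements,Vital,DEs related to vital-specific variables
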