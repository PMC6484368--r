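network,construct_kind,term,domain,definition
OHDSI,data_element,age at first observation period,Age,DE related to age-specific variables
OHDSI,data_element,age at death,Age,DE related to age-specific variables
OHDSI,data_element,age,Age,DE related to age-specific variables
OHDSI,data_element,care sites,Care Site,DE related to places of care variables
OHDSI,data_element,condition occurrence records,Condition,DE related to condition-specific variables
OHDSI,data_element,condition occurrence concepts,Condition,DE related to condition-specific variables
OHDSI,data_element,condition eras,Condition,DE related to condition-specific variables
OHDSI,data_element,condition era length,Condition,DE related to condition-specific variables
OHDSI,data_element,condition era concepts,Condition,DE related to condition-specific variables
OHDSI,data_element,death records,Death,DE related to death-specific variables
OHDSI,data_element,records of death,Death,DE related to death-specific variables
OHDSI,data_element,time from death,Death,DE related to death-specific variables
OHDSI,data_element,procedure cost records,Insurance,DE related to insurance-specific variables
OHDSI,data_element,total paid,Insurance,DE related to insurance-specific variables
OHDSI,data_element,total out-of-pocket,Insurance,DE related to insurance-specific variables
OHDSI,data_element,paid toward deductible,Insurance,DE related to insurance-specific variables
OHDSI,data_element,paid copay,Insurance,DE related to insurance-specific variables
OHDSI,data_element,paid coinsurance,Insurance,DE related to insurance-specific variables
OHDSI,data_element,paid by payer,Insurance,DE related to insurance-specific variables
OHDSI,data_element,paid by coordination of benefit,Insurance,DE related to insurance-specific variables
OHDSI,data_element,ingredient_cost,Insurance,DE related to insurance-specific variables
OHDSI,data_element,drug cost records,Insurance,DE related to insurance-specific variables
OHDSI,data_element,dispensing fee,Insurance,DE related to insurance-specific variables
OHDSI,data_element,average wholesale price,Insurance,DE related to insurance-specific variables
OHDSI,data_element,payer plan (days) of first payer plan period,Insurance,DE related to insurance-specific variables
OHDSI,data_element,refills,Medication,DE related to medication-specific variables
OHDSI,data_element,quantity,Medication,DE related to medication-specific variables
OHDSI,data_element,drug occurrence records,Medication,DE related to medication-specific variables
OHDSI,data_element,drug exposure records,Medication,DE related to medication-specific variables
OHDSI,data_element,drug exposure concepts,Medication,DE related to medication-specific variables
OHDSI,data_element,drug eras,Medication,DE related to medication-specific variables
OHDSI,data_element,drug era records,Medication,DE related to medication-specific variables
OHDSI,data_element,drug era length,Medication,DE related to medication-specific variables
OHDSI,data_element,drug era concepts,Medication,DE related to medication-specific variables
OHDSI,data_element,days_supply,Medication,DE related to medication-specific variables
OHDSI,data_element,numeric values,Numeric Values,DE related to an unspecified numeric values
OHDSI,data_element,records,Observations,DE related to observation-centric variables
OHDSI,data_element,observation records,Observations,DE related to observation-centric variables
OHDSI,data_element,observation occurrence records,Observations,DE related to observation-centric variables
OHDSI,data_element,observation occurrence concepts,Observations,DE related to observation-centric variables
OHDSI,data_element,observation (days) of first observation period,Observations,DE related to observation-centric variables
OHDSI,data_element,Persons,Person,DE that examines only persons
OHDSI,data_element,procedure occurrence records,Procedure,DE related to procedure-specific variables
OHDSI,data_element,Providers,Provider,DE related to provider-specific variables
OHDSI,data_element,visits,Visit,DE related to visit-record related variables
OHDSI,data_element,visit records,Visit,DE related to visit-record related variables
OHDSI,data_element,visit occurrence records,Visit,DE related to visit-record related variables
OHDSI,data_element,visit occurrence concepts,Visit,DE related to visit-record related variables
OHDSI,data_element,length of stay,Visit,DE related to visit-record related variables
OHDSI,function,Number of,Count,Measures the count of DE relative to a certain specification
OHDSI,function,Distribution of,Distribution,Measures the dispersion of DE across a certain specification
OHDSI,function,Length of,Time Length,Measures the time frame of DE given a certain specification
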