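network,construct_kind,term,domain,definition
CESR,function,Category,Category,Examines whether or not appropriate categories of a DE are correctly entered
CESR,function,Expected order of values,Consistency,Examines if a target DE follows an expected pattern with another DE
CESR,function,Compare to,Consistency,Examines if a target DE follows an expected pattern with another DE
CESR,function,Extra check,Consistency,Examines if a target DE follows an expected pattern with another DE
CESR,function,Consistency,Consistency,Examines if a target DE follows an expected pattern with another DE
CESR,function,Frequency,Count,Measures the count of a DE (either by the DE or categories of the DE)
CESR,function,Counts,Count,Measures the count of a DE (either by the DE or categories of the DE)
CESR,function,Number,Count,Measures the count of a DE (either by the DE or categories of the DE)
CESR,function,Cross tab,Cross tab,Cross-section of a target DE with other DEs
CESR,function,Distribution,Distribution,Examines context-specific dispersion of a DE
CESR,function,Exist,Existence,Examines if the DE itself is present
CESR,function,Existence,Existence,Examines if the DE itself is present
CESR,function,Link,Link,Examines if DE is linked correctly
CESR,function,Missing,Missing,Examines if a DE's entries are present
CESR,function,Not overlap,Overlap,Examines multiple locations of DE occurrence
CESR,function,Overlap,Overlap,Examines multiple locations of DE occurrence
CESR,function,Sum,Sum,Measures the sum of DEs (typically used for proportions that must add to 1)
CESR,function,Trend,Trend,Examines time fluctuation of a DE
CESR,function,Uniqueness,Uniqueness,Examines if DE duplicates are present
CESR,function,Length,Variable Length,Examines the variable length of a DE
CESR,function,Type,Variable Type,Examines how the DE is stored or defined (e.g. date format or integer)
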