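resource_id,name,aliases,line1,city,state,zip,roles
R001,Hope House,Hope House Shelter|Hope Hse,201 West Short Street,Lexington,KY,40507,emergency_shelter|transitional_housing
R002,New Start,New Start Center|New Start Recovery,415 Price Avenue,Lexington,KY,40508,residential_sud_treatment
R003,Harbor Light Mission,Harbor Light|The Harbor,960 Industry Road,Lexington,KY,40505,emergency_shelter
R004,Cornerstone Recovery Home,Cornerstone House,118 Loudon Avenue,Lexington,KY,40508,residential_sud_treatment|transitional_housing
R005,Open Door Shelter,Open Door,724 Winchester Road,Lexington,KY,40505,emergency_shelter
R006,Phoenix Rising House,Phoenix House Lexington,333 Versailles Road,Lexington,KY,40504,transitional_housing
R007,Grace Haven,Grace Haven Women's Center,52 Midland Place,Lexington,KY,40508,emergency_shelter|transitional_housing
R008,Stepping Stone Lodge,Stepping Stone,1400 Georgetown Street,Lexington,KY,40511,transitional_housing
R009,Riverbend Treatment Residence,Riverbend House,2050 Old Frankfort Pike,Lexington,KY,40510,residential_sud_treatment
R010,Shepherd's Inn,Shepherds Inn,640 East Third Street,Lexington,KY,40508,emergency_shelter
R011,Bluegrass Fresh Start,Fresh Start Bluegrass,88 Codell Drive,Lexington,KY,40509,residential_sud_treatment|transitional_housing
R012,Safe Harbor Family Shelter,Safe Harbor,310 Newtown Pike,Lexington,KY,40511,emergency_shelter
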