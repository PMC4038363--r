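"sex","variable","level","controls","cases"
"female","AGE","<=50",57,93
"female","AGE",">50",82,89
"female","SUNBURN","yes",71,118
"female","SUNBURN","no",68,64
"female","HAIRCOLOUR","black/brown",89,89
"female","HAIRCOLOUR","fair/blond/red",50,93
"female","EYECOLOUR","brown",25,20
"female","EYECOLOUR","hazel",30,31
"female","EYECOLOUR","green",20,29
"female","EYECOLOUR","grey/blue",64,102
"female","SKINCOLOUR","olive",22,7
"female","SKINCOLOUR","medium",53,57
"female","SKINCOLOUR","fair",64,118
"female","FRECKLING","none",77,73
"female","FRECKLING","few",45,60
"female","FRECKLING","moderate",10,18
"female","FRECKLING","many",7,31
"female","MOLES_RARM","0",96,88
"female","MOLES_RARM","1",23,30
"female","MOLES_RARM","2",11,22
"female","MOLES_RARM","3+",8,41
"female","FAMHXMOLES","yes",56,116
"female","FAMHXMOLES","no",83,66
"female","NMSC","yes",5,20
"female","NMSC","no",134,162
"male","AGE","<=50",69,53
"male","AGE",">50",62,133
"male","EYECOLOUR","brown",17,39
"male","EYECOLOUR","hazel",29,30
"male","EYECOLOUR","green",17,30
"male","EYECOLOUR","grey/blue",68,87
"male","SKINCOLOUR","olive",12,17
"male","SKINCOLOUR","medium",56,60
"male","SKINCOLOUR","fair",63,109
"male","NMSC","yes",5,28
"male","NMSC","no",126,158
"male","OCC18","indoor",44,43
"male","OCC18","indoor and outdoor",52,67
"male","OCC18","outdoor",35,74
"male","OCC_GT18","indoor",44,43
"male","OCC_GT18","indoor and outdoor",48,61
"male","OCC_GT18","outdoor",39,80
"male","BIRTHPLACE","outside NZ",23,15
"male","BIRTHPLACE","in NZ",108,171
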