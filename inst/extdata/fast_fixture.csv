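"encounter_id","score","tfc_high"
"enc001",0,TRUE
"enc002",1,TRUE
"enc003",1,TRUE
"enc004",1,TRUE
"enc005",2,TRUE
"enc006",2,TRUE
"enc007",3,TRUE
"enc008",3,TRUE
"enc009",3,TRUE
"enc010",3,TRUE
"enc011",3,TRUE
"enc012",3,TRUE
"enc013",3,TRUE
"enc014",3,TRUE
"enc015",3,TRUE
"enc016",3,TRUE
"enc017",4,TRUE
"enc018",4,TRUE
"enc019",4,TRUE
"enc020",4,TRUE
"enc021",4,TRUE
"enc022",4,TRUE
"enc023",4,TRUE
"enc024",4,TRUE
"enc025",4,TRUE
"enc026",4,TRUE
"enc027",4,TRUE
"enc028",4,TRUE
"enc029",4,TRUE
"enc030",4,TRUE
"enc031",5,TRUE
"enc032",5,TRUE
"enc033",5,TRUE
"enc034",5,TRUE
"enc035",5,TRUE
"enc036",5,TRUE
"enc037",5,TRUE
"enc038",5,TRUE
"enc039",5,TRUE
"enc040",5,TRUE
"enc041",5,TRUE
"enc042",5,TRUE
"enc043",5,TRUE
"enc044",5,TRUE
"enc045",5,TRUE
"enc046",5,TRUE
"enc047",5,TRUE
"enc048",5,TRUE
"enc049",5,TRUE
"enc050",5,TRUE
"enc051",6,TRUE
"enc052",6,TRUE
"enc053",6,TRUE
"enc054",6,TRUE
"enc055",6,TRUE
"enc056",6,TRUE
"enc057",6,TRUE
"enc058",6,TRUE
"enc059",6,TRUE
"enc060",6,TRUE
"enc061",7,TRUE
"enc062",7,TRUE
"enc063",7,TRUE
"enc064",7,TRUE
"enc065",7,TRUE
"enc066",7,TRUE
"enc067",7,TRUE
"enc068",7,TRUE
"enc069",7,TRUE
"enc070",8,TRUE
"enc071",8,TRUE
"enc072",8,TRUE
"enc073",8,TRUE
"enc074",8,TRUE
"enc075",8,TRUE
"enc076",8,TRUE
"enc077",8,TRUE
"enc078",8,TRUE
"enc079",0,FALSE
"enc080",0,FALSE
"enc081",0,FALSE
"enc082",0,FALSE
"enc083",0,FALSE
"enc084",0,FALSE
"enc085",0,FALSE
"enc086",0,FALSE
"enc087",0,FALSE
"enc088",0,FALSE
"enc089",0,FALSE
"enc090",0,FALSE
"enc091",1,FALSE
"enc092",1,FALSE
"enc093",1,FALSE
"enc094",1,FALSE
"enc095",1,FALSE
"enc096",1,FALSE
"enc097",1,FALSE
"enc098",1,FALSE
"enc099",2,FALSE
"enc100",2,FALSE
"enc101",2,FALSE
"enc102",2,FALSE
"enc103",2,FALSE
"enc104",2,FALSE
"enc105",2,FALSE
"enc106",3,FALSE
"enc107",3,FALSE
"enc108",3,FALSE
"enc109",3,FALSE
"enc110",3,FALSE
"enc111",4,FALSE
"enc112",4,FALSE
"enc113",4,FALSE
"enc114",4,FALSE
"enc115",5,FALSE
"enc116",7,FALSE
"enc117",8,FALSE
"enc118",8,FALSE
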