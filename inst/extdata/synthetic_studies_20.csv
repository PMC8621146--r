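"study_id","disease","tp","fp","fn","tn","fri","training_n","resolution_px","model_class","control_type","n_diseases","validation","excl_flags"
"syn01","Cornelia de Lange syndrome",77,4,4,66,"7.443",120,"10000","deep_learning","healthy",1,"external","external_validation;unclear_sampling"
"syn02","Cornelia de Lange syndrome",35,29,3,170,"7.443",3465,"90000","deep_learning","healthy",1,"external","external_validation;unclear_sampling"
"syn03","Cornelia de Lange syndrome",72,25,1,188,"7.443",60,"","unreported","healthy",1,"external","external_validation;unclear_model;unclear_reference"
"syn04","Turner syndrome",33,11,22,121,"3.36",49,"22500","non_deep_learning","healthy",1,"external","external_validation;unclear_sampling"
"syn05","Turner syndrome",75,15,50,189,"3.36",1500,"160000","deep_learning","healthy",1,"external","external_validation;unclear_sampling"
"syn06","Down syndrome",78,8,1,133,"9",30,"12100","non_deep_learning","healthy",1,"external","external_validation;unclear_reference"
"syn07","Down syndrome",104,13,2,137,"9",90,"","unreported","healthy",1,"external","external_validation;unclear_model"
"syn08","Down syndrome",234,13,8,172,"9",2200,"250000","deep_learning","healthy",1,"external","external_validation"
"syn09","Angelman syndrome",103,4,30,61,"6",300,"40000","non_deep_learning","healthy",1,"internal",""
"syn10","Acromegaly",149,17,2,161,"8",75,"","unreported","other_diseases",1,"internal","unclear_model;unclear_reference"
"syn11","Acromegaly",59,6,4,89,"8",1100,"14400","deep_learning","other_diseases",1,"internal",""
"syn12","Acromegaly",150,9,6,80,"8",640,"105000","non_deep_learning","other_diseases",1,"internal",""
"syn13","Acromegaly",141,10,9,144,"8",210,"","unreported","other_diseases",1,"internal","unclear_model"
"syn14","Cushing's syndrome",91,17,18,196,"5",2800,"20164","deep_learning","other_diseases",1,"internal",""
"syn15","Cushing's syndrome",41,12,7,85,"5",55,"28900","non_deep_learning","other_diseases",1,"internal","unclear_reference"
"syn16","Fetal alcohol spectrum disorders",133,7,31,53,"4",430,"","unreported","other_diseases",1,"internal","unclear_model"
"syn17","multiple",24,11,3,194,"",130,"62500","deep_learning","other_diseases",3,"internal",""
"syn18","multiple",113,4,26,33,"",980,"96100","non_deep_learning","other_diseases",5,"internal",""
"syn19","multiple",67,8,7,109,"",3100,"","non_deep_learning","other_diseases",2,"internal",""
"syn20","multiple",180,20,14,169,"",860,"17689","non_deep_learning","other_diseases",10,"internal",""
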