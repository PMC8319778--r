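item,seed_term
satisfaction,accomplish
satisfaction,achieve
satisfaction,satisfaction
satisfaction,satisfied
satisfaction,enjoy
satisfaction,content
satisfaction,contentment
satisfaction,accomplishment
satisfaction,love
satisfaction,proud
satisfaction,inspired
satisfaction,inspiring
satisfaction,enthuse
satisfaction,affirm
breadth,activity
breadth,active
breadth,participate
breadth,involved
breadth,event
breadth,powerlifting
breadth,water coloring
breadth,exercise
breadth,sport
breadth,basketball
breadth,restaurant
breadth,hobby
breadth,craft
breadth,art
breadth,music
breadth,instrument
breadth,piano
decisions,decision
decisions,planning
decisions,plan
decisions,contest
decisions,competition
decisions,opportunity
decisions,chance
decisions,spontaneous
decisions,whim
decisions,spur
decisions,attentive
decisions,affirm
decisions,commit
decisions,focus
accomplishment,goals
accomplishment,accomplish
accomplishment,progress
accomplishment,goal
accomplishment,achieve
accomplishment,effort
accomplishment,content
accomplishment,contentment
accomplishment,accomplishment
accomplishment,proud
long-term,goals
long-term,progress
long-term,goal
long-term,effort
long-term,planning
long-term,plan
long-term,challenge
long-term,attentive
long-term,birth
long-term,commit
long-term,change
long-term,invest
long-term,life
long-term,payoff
long-term,benefit
effort,effort
effort,enjoy
effort,excited
effort,energized
effort,energizing
effort,love
effort,contest
effort,competition
effort,challenge
effort,chance
effort,fun
effort,enthusiastic
effort,inspired
effort,inspiring
effort,enthuse
effort,event
effort,affirm
effort,commit
effort,change
effort,focus
effort,fuel
effort,invest
effort,invigorate
structure,goals
structure,progress
structure,goal
structure,planning
structure,plan
structure,structure
structure,attentive
structure,event
structure,routine
structure,schedule
structure,regular
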